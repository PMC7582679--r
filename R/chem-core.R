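## Low-level OpenBabel-backed chemistry helpers shared by the compound-space
## functions.  Everything here is deterministic: OpenBabel's canonical SMILES
## writer and its 3D builder contain no random stages.

## Canonicalize one or more SMILES strings.  Returns NA_character_ for
## strings OpenBabel cannot parse.  Conversions run one molecule at a time
## because OpenBabel aborts a batch at the first bad record.
ob_canonical <- function(smiles, options = NULL) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    src <- paste0(trimws(s), " m\n")
    out <- try(
      suppressWarnings(
        if (is.null(options)) ChemmineOB::convertFormat("SMI", "CAN", src)
        else ChemmineOB::convertFormat("SMI", "CAN", src, options = options)
      ),
      silent = TRUE
    )
    if (inherits(out, "try-error") || length(out) == 0) return(NA_character_)
    line <- trimws(sub("[ \t].*$", "", trimws(out[[1]])))
    if (!nzchar(line)) NA_character_ else line
  }, character(1), USE.NAMES = FALSE)
}

## Canonical SMILES with all stereo descriptors removed (constitution only).
ob_canonical_nostereo <- function(smiles) {
  ob_canonical(gsub("[/\\\\]", "", gsub("@", "", smiles)))
}

## --- SMILES tokenization -------------------------------------------------

## Split a SMILES string into atom tokens and the literal text between them.
## Returns a data.frame with one row per segment, in string order.
.atom_regex <- "\\[[^]]+\\]|Cl|Br|[BCNOPSFIbcnosp]"

tokenize_smiles <- function(s) {
  m <- gregexpr(.atom_regex, s)[[1]]
  if (m[1] == -1) {
    return(data.frame(text = s, is_atom = FALSE, stringsAsFactors = FALSE))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  segs <- list()
  pos <- 1L
  for (i in seq_along(starts)) {
    if (starts[i] > pos) {
      segs[[length(segs) + 1L]] <- list(text = substr(s, pos, starts[i] - 1L), is_atom = FALSE)
    }
    segs[[length(segs) + 1L]] <- list(text = substr(s, starts[i], starts[i] + lens[i] - 1L), is_atom = TRUE)
    pos <- starts[i] + lens[i]
  }
  if (pos <= nchar(s)) {
    segs[[length(segs) + 1L]] <- list(text = substr(s, pos, nchar(s)), is_atom = FALSE)
  }
  data.frame(
    text = vapply(segs, `[[`, character(1), "text"),
    is_atom = vapply(segs, `[[`, logical(1), "is_atom"),
    stringsAsFactors = FALSE
  )
}

## Element symbol, aromaticity, explicit-H count, charge and stereo flag of
## one atom token.
parse_atom_token <- function(tok) {
  if (startsWith(tok, "[")) {
    body <- substr(tok, 2, nchar(tok) - 1L)
    body <- sub("^[0-9]+", "", body)  # isotope
    elem <- regmatches(body, regexpr("^[A-Za-z][a-z]?", body))[1]
    ## Trailing lowercase of a two-letter match may actually be an H count
    ## marker (e.g. [CH3]); only Cl/Br/Si-like true two-letter symbols keep it.
    if (nchar(elem) == 2 && !(elem %in% c("Cl", "Br", "Si", "Se", "As", "Na",
                                          "Li", "Mg", "Ca", "Fe", "Zn", "Al",
                                          "se", "as"))) {
      elem <- substr(elem, 1, 1)
    }
    rest <- substr(body, nchar(elem) + 1L, nchar(body))
    hcount <- 0L
    hm <- regmatches(rest, regexpr("H[0-9]*", rest))
    if (length(hm) && nzchar(hm)) {
      hcount <- if (hm == "H") 1L else as.integer(sub("H", "", hm))
    }
    charge <- 0L
    if (grepl("\\+", rest)) {
      cm <- regmatches(rest, regexpr("\\+[0-9]*", rest))
      charge <- if (cm == "+") sum(strsplit(rest, "")[[1]] == "+") else as.integer(sub("\\+", "", cm))
    } else if (grepl("-", rest)) {
      cm <- regmatches(rest, regexpr("-[0-9]*", rest))
      charge <- -(if (cm == "-") sum(strsplit(rest, "")[[1]] == "-") else as.integer(sub("-", "", cm)))
    }
    list(element = paste0(toupper(substr(elem, 1, 1)), substr(elem, 2, nchar(elem))),
         aromatic = elem %in% c("b", "c", "n", "o", "p", "s", "se", "as"),
         hcount = hcount, explicit_h = TRUE, charge = charge,
         stereo = grepl("@", tok))
  } else {
    list(element = if (tok %in% c("Cl", "Br")) tok else toupper(tok),
         aromatic = tok %in% c("b", "c", "n", "o", "p", "s"),
         hcount = NA_integer_, explicit_h = FALSE, charge = 0L,
         stereo = FALSE)
  }
}

.default_valences <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

.atomic_numbers <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12, Al = 13,
  Si = 14, P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Fe = 26, Zn = 30,
  Se = 34, Br = 35, I = 53
)

## Build a heavy-atom molecular graph from a canonical SMILES string.
## Atom order in the ChemmineR/OpenBabel SDF equals SMILES token order, which
## lets us line up token-level attributes (aromaticity, charge, stereo marks)
## with the SDF bond table.
mol_graph <- function(smiles) {
  toks <- tokenize_smiles(smiles)
  atom_rows <- which(toks$is_atom)
  parsed <- lapply(toks$text[atom_rows], parse_atom_token)
  n <- length(atom_rows)
  if (n == 0) tf_input_error(sprintf("no atoms in SMILES '%s'", smiles))

  sdf <- try(suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles, "m"))), silent = TRUE)
  if (inherits(sdf, "try-error")) {
    tf_input_error(sprintf("SMILES '%s' could not be parsed into a molecule", smiles))
  }
  bb <- ChemmineR::bondblock(sdf[[1]])
  ab <- ChemmineR::atomblock(sdf[[1]])
  if (nrow(ab) != n) {
    tf_computation_error(sprintf(
      "atom-count mismatch between SMILES tokens (%d) and molecule (%d) for '%s'",
      n, nrow(ab), smiles))
  }
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }

  element <- vapply(parsed, `[[`, character(1), "element")
  aromatic <- vapply(parsed, `[[`, logical(1), "aromatic")
  charge <- vapply(parsed, `[[`, integer(1), "charge")
  stereo <- vapply(parsed, `[[`, logical(1), "stereo")

  bondsum <- numeric(n)
  degree <- integer(n)
  for (i in seq_len(nrow(bonds))) {
    o <- bonds$order[i]
    bondsum[bonds$a1[i]] <- bondsum[bonds$a1[i]] + o
    bondsum[bonds$a2[i]] <- bondsum[bonds$a2[i]] + o
    degree[bonds$a1[i]] <- degree[bonds$a1[i]] + 1L
    degree[bonds$a2[i]] <- degree[bonds$a2[i]] + 1L
  }

  hcount <- integer(n)
  for (i in seq_len(n)) {
    if (parsed[[i]]$explicit_h) {
      hcount[i] <- parsed[[i]]$hcount
    } else {
      vals <- .default_valences[[element[i]]]
      if (is.null(vals)) {
        hcount[i] <- 0L
      } else {
        ## neutral-organic adjustment: N+ gains a bond, O-/S- lose one
        vals <- vals + charge[i] * (if (element[i] %in% c("N", "P")) 1 else
                                    if (element[i] %in% c("O", "S")) 1 else 0)
        v <- vals[vals >= bondsum[i]]
        hcount[i] <- if (length(v)) as.integer(min(v) - bondsum[i]) else 0L
      }
    }
  }

  ring_atom <- rep(FALSE, n)
  if (nrow(bonds) > 0) {
    g <- igraph::graph_from_data_frame(bonds[, c("a1", "a2")], directed = FALSE,
                                       vertices = data.frame(name = seq_len(n)))
    br <- igraph::bridges(g)
    cyc_edges <- setdiff(seq_len(nrow(bonds)), as.integer(br))
    ring_atom[unique(c(bonds$a1[cyc_edges], bonds$a2[cyc_edges]))] <- TRUE
  }

  list(
    smiles = smiles,
    tokens = toks,
    atom_token_rows = atom_rows,
    element = element,
    aromatic = aromatic,
    charge = charge,
    stereo_marked = stereo,
    hcount = hcount,
    degree = degree,
    bondsum = bondsum,
    ring_atom = ring_atom,
    bonds = bonds
  )
}

## Count heavy atoms of a SMILES fragment (used by the salt-stripping rule).
count_heavy_atoms <- function(smiles) {
  toks <- tokenize_smiles(smiles)
  sum(toks$is_atom)
}

## Substructure screen via the OpenBabel command-line filter (`obabel -s`);
## returns a logical vector, one entry per input SMILES.
matches_substructure <- function(smiles, smarts) {
  if (Sys.which("obabel") == "") {
    tf_computation_error("the 'obabel' executable is required for substructure matching")
  }
  inp <- tempfile(fileext = ".smi")
  out <- tempfile(fileext = ".smi")
  on.exit(unlink(c(inp, out)))
  writeLines(paste(smiles, seq_along(smiles)), inp)
  system2("obabel", c("-ismi", inp, "-osmi", "-O", out, "-s", shQuote(smarts)),
          stdout = FALSE, stderr = FALSE)
  hits <- if (file.exists(out)) readLines(out) else character(0)
  hit_ids <- as.integer(sub("^.*[ \t]", "", hits))
  seq_along(smiles) %in% hit_ids
}

## Molecular weight via OpenBabel property computation.
ob_molweight <- function(smiles) {
  sdf <- try(suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles, "m"))), silent = TRUE)
  if (inherits(sdf, "try-error")) return(NA_real_)
  p <- try(suppressWarnings(ChemmineR::propOB(sdf)), silent = TRUE)
  if (inherits(p, "try-error")) return(NA_real_)
  as.numeric(p$MW[1])
}
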