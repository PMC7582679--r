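# Consensus scoring, known-space subtraction, selection criteria,
# enrichment and activity calling.

make_known <- function(pairs, weights = NULL) {
  rec <- data.frame(
    compound_id = vapply(pairs, `[[`, character(1), 1),
    target_id = vapply(pairs, `[[`, character(1), 2),
    stringsAsFactors = FALSE
  )
  rec$weight <- rep(weights %||% 1L, length.out = nrow(rec))
  rec$assay_ids <- rep(NA_character_, nrow(rec))
  rec$protein_entry <- rep(NA_character_, nrow(rec))
  rec$pathways <- rep(NA_character_, nrow(rec))
  structure(list(records = rec, resolution_failures = character(0)),
            class = "known_space")
}

test_that("a pair asserted by the anchor plus two servers scores CS = 3", {
  mats <- list(
    bool_matrix("phdb", list(c("c1", "TA")), is_anchor = TRUE),
    bool_matrix("server_a", list(c("c1", "TA"), c("c2", "TB"))),
    bool_matrix("server_b", list(c("c1", "TA")))
  )
  recs <- assemble_predicted_space(mats)
  row <- recs[recs$compound_id == "c1" & recs$target_id == "TA", ]
  expect_equal(row$cs, 3)
  expect_true(row$anchor_hit)
  expect_true(row$eligible)
  # a pair seen by a single non-anchor server
  other <- recs[recs$compound_id == "c2", ]
  expect_equal(other$cs, 1)
  expect_false(other$anchor_hit)
  expect_false(other$eligible)
})

test_that("consensus scores equal a brute-force per-pair method count", {
  withr::with_seed(6, {
    methods <- paste0("m", 1:4)
    pairs <- expand.grid(compound_id = paste0("c", 1:3),
                         target_id = paste0("T", 1:2), stringsAsFactors = FALSE)
    asserted <- lapply(methods, function(m) {
      pairs[runif(nrow(pairs)) < 0.6, , drop = FALSE]
    })
  })
  mats <- lapply(seq_along(methods), function(i) {
    e <- asserted[[i]]
    if (nrow(e) == 0) e <- pairs[1, , drop = FALSE]
    bool_matrix(methods[i],
                lapply(seq_len(nrow(e)), function(j) c(e$compound_id[j], e$target_id[j])),
                is_anchor = i == 1)
  })
  recs <- assemble_predicted_space(mats)
  for (i in seq_len(nrow(recs))) {
    n_manual <- sum(vapply(mats, function(m) {
      any(m$entries$compound_id == recs$compound_id[i] &
            m$entries$target_id == recs$target_id[i])
    }, logical(1)))
    expect_equal(recs$cs[i], n_manual)
  }
  # CS conservation: total CS equals total surviving entries across methods
  expect_equal(sum(recs$cs), sum(vapply(mats, function(m) nrow(m$entries), numeric(1))))
})

test_that("zero or multiple anchors are fatal", {
  m1 <- bool_matrix("a", list(c("c1", "T1")))
  m2 <- bool_matrix("b", list(c("c1", "T1")), is_anchor = TRUE)
  m3 <- bool_matrix("c", list(c("c1", "T1")), is_anchor = TRUE)
  expect_error(assemble_predicted_space(list(m1)), "anchor")
  expect_error(assemble_predicted_space(list(m2, m3)), "anchor")
})

test_that("known-space subtraction removes pairs, is idempotent, honors parents", {
  mats <- list(
    bool_matrix("phdb", list(c("c1", "TA"), c("c1", "TB"), c("c2_s1", "TC")),
                is_anchor = TRUE),
    bool_matrix("srv", list(c("c1", "TA")))
  )
  recs <- assemble_predicted_space(mats)
  known <- make_known(list(c("c1", "TA"), c("c2", "TC")))
  sub <- suppressMessages(subtract_known(recs, known,
                                         parent_map = c(c2_s1 = "c2")))
  expect_setequal(paste(sub$compound_id, sub$target_id), "c1 TB")
  # idempotence
  sub2 <- suppressMessages(subtract_known(sub, known, parent_map = c(c2_s1 = "c2")))
  expect_equal(sub, sub2)
  # empty known space: identity
  id <- suppressMessages(subtract_known(recs, make_known(list())))
  expect_equal(nrow(id), nrow(recs))
})

test_that("criterion I keeps eligible panel records at or above the CS floor", {
  mats <- list(
    bool_matrix("phdb", list(c("p1", "TA"), c("p2", "TA"), c("x9", "TA")),
                is_anchor = TRUE),
    bool_matrix("s1", list(c("p1", "TA"), c("p2", "TB"), c("x9", "TA"))),
    bool_matrix("s2", list(c("p1", "TA")))
  )
  recs <- assemble_predicted_space(mats)
  ci <- criterion_I(recs, panel = c("p1", "p2"), min_cs = 2)
  expect_named(ci, "TA")
  expect_equal(ci$TA$compound_id, "p1")
  expect_equal(ci$TA$cs, 3)
  # p2/TB lacks the anchor: excluded although cs-eligible panel compound
  expect_false("TB" %in% names(ci))
  expect_error(criterion_I(recs, panel = character(0)), "panel")
})

test_that("criterion II ranks by frequency with shared ranks on ties", {
  pairs <- c(
    lapply(paste0("c", 1:5), function(c) c(c, "TBIG")),
    lapply(paste0("c", 1:3), function(c) c(c, "TMIDA")),
    lapply(paste0("c", 4:6), function(c) c(c, "TMIDB")),
    list(c("c1", "TSMALL"))
  )
  mats <- list(bool_matrix("phdb", pairs, is_anchor = TRUE),
               bool_matrix("srv", pairs))
  recs <- assemble_predicted_space(mats)
  rk <- criterion_II(recs, cs_levels = 2L)
  expect_equal(rk$target_id[1], "TBIG")
  expect_equal(rk$frequency[1], 5)
  expect_equal(rk$rank[1], 1)
  mids <- rk[rk$target_id %in% c("TMIDA", "TMIDB"), ]
  expect_equal(mids$rank, c(2L, 2L))
  expect_equal(mids$target_id, c("TMIDA", "TMIDB"))  # lexicographic display
  expect_equal(rk$rank[rk$target_id == "TSMALL"], 4L)
  # frequency monotonicity across CS levels
  rk23 <- criterion_II(recs, cs_levels = c(2L, 3L))
  for (tg in unique(rk23$target_id)) {
    f2 <- rk23$frequency[rk23$cs_level == 2 & rk23$target_id == tg]
    f3 <- rk23$frequency[rk23$cs_level == 3 & rk23$target_id == tg]
    if (length(f2) && length(f3)) expect_lte(f3, f2)
  }
})

test_that("criterion III flags novelty and collects pathway evidence", {
  mats <- list(bool_matrix("phdb", list(c("p1", "ALOX5"), c("p1", "PTGS1"),
                                        c("p1", "NEW1")), is_anchor = TRUE),
               bool_matrix("srv", list(c("p1", "ALOX5"), c("p1", "PTGS1"),
                                       c("p1", "NEW1"))))
  recs <- assemble_predicted_space(mats)
  known <- make_known(list(c("p1", "PTGS1")))
  pw <- data.frame(
    target_id = c("ALOX5", "PTGS1", "NEW1"),
    pathway = c("arachidonic acid metabolism", "arachidonic acid metabolism",
                "steroid metabolism")
  )
  c3 <- criterion_III(recs, known, pw, panel = "p1")
  expect_true(c3$novelty[c3$target_id == "ALOX5"])
  expect_false(c3$novelty[c3$target_id == "PTGS1"])
  expect_equal(c3$related_targets[c3$target_id == "ALOX5"], "PTGS1")
  expect_equal(c3$related_targets[c3$target_id == "NEW1"], "")
  # brute-force pairwise pathway intersection over the fixture
  for (i in seq_len(nrow(c3))) {
    tg <- c3$target_id[i]
    own <- pw$pathway[pw$target_id == tg]
    manual <- sort(setdiff(unique(pw$target_id[pw$pathway %in% own]), tg))
    listed <- strsplit(c3$related_targets[i], ";")[[1]]
    expect_setequal(listed, manual)
  }
})

test_that("selection report combines the four criteria", {
  mats <- list(bool_matrix("phdb", list(c("p1", "TGOOD"), c("p1", "TKNOWN"),
                                        c("p1", "TNOASSAY")), is_anchor = TRUE),
               bool_matrix("srv", list(c("p1", "TGOOD"), c("p1", "TKNOWN"),
                                       c("p1", "TNOASSAY"))))
  recs <- assemble_predicted_space(mats)
  known <- make_known(list(c("p1", "TKNOWN")))
  avail <- data.frame(target_id = c("TGOOD", "TKNOWN", "TNOASSAY"),
                      assay_available = c(TRUE, TRUE, FALSE))
  rep <- selection_report(recs, known,
                          data.frame(target_id = character(0), pathway = character(0)),
                          panel = "p1", assay_availability = avail)
  expect_true(rep$selected[rep$target_id == "TGOOD"])
  expect_false(rep$selected[rep$target_id == "TKNOWN"])    # not novel
  expect_false(rep$selected[rep$target_id == "TNOASSAY"])  # no assay
  # the invariant: selected implies assay available and novel
  expect_true(all(!rep$selected | (rep$assay_available & rep$novelty)))
})

test_that("a perfect ranking attains the maximal enrichment factor", {
  # universe of 20 pairs, 4 known, ranked first by construction
  pairs <- expand.grid(compound_id = paste0("c", 1:4),
                       target_id = paste0("T", 1:5), stringsAsFactors = FALSE)
  pairs$score <- seq(nrow(pairs), 1)  # higher is better
  known_pairs <- lapply(1:4, function(i) c(pairs$compound_id[i], pairs$target_id[i]))
  m <- prediction_matrix(pairs, "perfect", "higher_better", is_anchor = TRUE)
  recs <- assemble_predicted_space(list(binarize(m, 0)), min_cs = 1)
  known <- make_known(known_pairs)
  ef <- enrichment(recs, list(m), known, top_k = 4)
  expect_equal(ef$ef[ef$method == "perfect"], 20 / 4)
  expect_equal(ef$recovered[ef$method == "perfect"], 4)
  expect_error(enrichment(recs, list(m), make_known(list()), 4), "non-empty")
})

test_that("random rankings have enrichment factors near 1", {
  withr::with_seed(31, {
    pairs <- expand.grid(compound_id = sprintf("c%03d", 1:40),
                         target_id = paste0("T", 1:25), stringsAsFactors = FALSE)
    pairs$score <- runif(nrow(pairs))
    known_idx <- sample.int(nrow(pairs), 100)
  })
  known <- make_known(lapply(known_idx, function(i) {
    c(pairs$compound_id[i], pairs$target_id[i])
  }))
  m <- prediction_matrix(pairs, "rand", "higher_better", is_anchor = TRUE)
  recs <- assemble_predicted_space(list(binarize(m, 0)), min_cs = 1)
  ef <- enrichment(recs, list(m), known, top_k = 250)
  expect_gt(ef$ef[ef$method == "rand"], 0.5)
  expect_lt(ef$ef[ef$method == "rand"], 2.0)
})

test_that("activity calls follow the inhibition rules", {
  tab <- data.frame(
    compound_id = c("2", "1", "1", "2", "10", "4"),
    target_id = c("ALOX5", "HSD17B2", "AROMATASE", "PTGS1", "ALOX5", "AKR1C3"),
    mean = c(99.2, -50.7, 13.8, 48.1, 7.7, 34.4),
    sd = c(1.2, 22.7, 2.0, 12.0, 6.0, 5.1)
  )
  calls <- classify_assay_results(tab)
  expect_equal(calls$call, c(
    "active",    # 99.2 +/- 1.2: strong, tight
    "inactive",  # negative mean
    "inactive",  # below the 30% floor
    "inactive",  # relative sd 24.9% > 20%
    "inactive",  # 7.7% below the floor
    "active"     # 34.4 +/- 5.1: rel sd 14.8%
  ))
  expect_error(classify_assay_results(transform(tab, sd = -1)), "negative")
})

test_that("confirmed targets are counted as distinct targets with an active call", {
  calls <- classify_assay_results(data.frame(
    compound_id = c("a", "b", "c", "d"),
    target_id = c("T1", "T1", "T1", "T2"),
    mean = c(50, 60, 10, 5), sd = c(2, 3, 1, 1)
  ))
  expect_equal(confirmed_target_count(calls), 1)
  none <- classify_assay_results(data.frame(
    compound_id = "a", target_id = "T1", mean = 5, sd = 1))
  expect_equal(confirmed_target_count(none), 0)
})
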