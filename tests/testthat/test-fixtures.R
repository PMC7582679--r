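# Synthetic fixture generators: determinism, scaffold containment,
# similarity structure of the planted truth, and backend-table construction.

small_spec <- fixture_spec(seed = 5, n_compounds = 10, n_targets = 6,
                           n_planted_targets = 2, ligands_per_target = 4,
                           known_fraction = 0.5)

test_that("generators are pure functions of the fixture spec", {
  l1 <- generate_library(small_spec)
  l2 <- generate_library(small_spec)
  expect_identical(l1, l2)
  r1 <- generate_reference_sets(small_spec, l1)
  r2 <- generate_reference_sets(small_spec, l1)
  expect_identical(r1, r2)
  b1 <- generate_backend_tables(small_spec, l1, r1$truth)
  b2 <- generate_backend_tables(small_spec, l1, r1$truth)
  expect_identical(b1, b2)
  m1 <- generate_method_noise(small_spec, l1, r1$truth)
  m2 <- generate_method_noise(small_spec, l1, r1$truth)
  expect_identical(m1, m2)
})

test_that("fixture files are byte-identical across two runs with one spec", {
  d1 <- tempfile(); d2 <- tempfile()
  generate_fixture_set(small_spec, d1)
  generate_fixture_set(small_spec, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 5)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("a one-compound library is the bare scaffold", {
  one <- generate_library(fixture_spec(seed = 1, n_compounds = 1))
  expect_equal(one$smiles, fixture_spec(seed = 1)$scaffold)
})

test_that("every generated library molecule contains the scaffold", {
  lib <- generate_library(small_spec)
  expect_true(all(tarfish:::matches_substructure(lib$smiles, small_spec$scaffold)))
  expect_equal(anyDuplicated(tarfish:::ob_canonical(lib$smiles)), 0)
})

test_that("an over-greedy request fails with the achievable maximum", {
  expect_error(generate_library(fixture_spec(seed = 1, n_compounds = 5000)),
               "distinct molecules")
})

test_that("planted sets are self-similar and resemble the library", {
  lib <- generate_library(small_spec)
  refs <- generate_reference_sets(small_spec, lib)
  ref <- refs$reference
  fps_lib <- fingerprint_set(tarfish:::ob_canonical(lib$smiles))$circular
  fps_ref <- fingerprint_set(tarfish:::ob_canonical(ref$smiles))$circular
  planted <- grepl("^TP", ref$target_id)

  # intra-set similarity of a planted set exceeds planted-vs-decoy similarity
  tp1 <- fps_ref[ref$target_id == "TP01", , drop = FALSE]
  td <- fps_ref[!planted, , drop = FALSE]
  intra <- tanimoto_matrix(tp1, tp1)
  inter <- tanimoto_matrix(tp1, td)
  expect_gt(mean(intra[upper.tri(intra)]), mean(inter))

  # truth pairs (library vs planted ligands) are more similar than
  # library-vs-decoy pairs
  truth_sim <- mean(tanimoto_matrix(fps_lib, fps_ref[planted, , drop = FALSE]))
  decoy_sim <- mean(tanimoto_matrix(fps_lib, td))
  expect_gt(truth_sim, decoy_sim)
})

test_that("no planted targets means an empty truth table", {
  spec0 <- fixture_spec(seed = 5, n_compounds = 6, n_targets = 3,
                        n_planted_targets = 0, ligands_per_target = 3)
  refs <- generate_reference_sets(spec0, generate_library(spec0))
  expect_equal(nrow(refs$truth), 0)
})

test_that("backend tables expose the known fraction with per-pair record counts", {
  lib <- generate_library(small_spec)
  refs <- generate_reference_sets(small_spec, lib)
  bk <- generate_backend_tables(small_spec, lib, refs$truth)
  expect_equal(nrow(bk$exposed), round(0.5 * nrow(refs$truth)))
  # active single-protein records per exposed pair lie in 1..4
  act <- bk$assays[bk$assays$activity_flag == "active" &
                     !grepl(";", bk$assays$gene_names), ]
  cid_to_compound <- setNames(lib$compound_id, bk$compounds$cid)
  tally <- table(paste(cid_to_compound[act$cid], act$gene_names))
  exposed_keys <- paste(bk$exposed$compound_id, bk$exposed$target_id)
  expect_setequal(names(tally), exposed_keys)
  expect_true(all(tally >= 1 & tally <= 4))
  # distractor records exist and are filtered by construction
  expect_gt(sum(grepl(";", bk$assays$gene_names)), 0)
  expect_gt(sum(bk$assays$activity_flag == "inactive"), 0)

  # mining the fixture backend recovers exactly the exposed subset
  dir <- tempfile()
  dir.create(dir)
  for (nm in c("compounds", "assays", "proteins", "pathways")) {
    write.csv(bk[[nm]], file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  std <- standardize_library(make_library(lib$compound_id, lib$smiles))
  space <- suppressMessages(build_known_space(std, fixture_backend(dir)))
  expect_setequal(paste(space$records$compound_id, space$records$target_id),
                  exposed_keys)
  expect_equal(sum(space$records$weight), nrow(act))
})

test_that("zero known fraction leaves only distractor assays", {
  spec0 <- fixture_spec(seed = 5, n_compounds = 8, n_targets = 4,
                        n_planted_targets = 2, ligands_per_target = 3,
                        known_fraction = 0)
  lib <- generate_library(spec0)
  refs <- generate_reference_sets(spec0, lib)
  bk <- generate_backend_tables(spec0, lib, refs$truth)
  ok <- bk$assays$activity_flag == "active" & !grepl(";", bk$assays$gene_names)
  expect_equal(sum(ok), 0)
})

test_that("noise-free methods emit exactly the truth set", {
  spec0 <- fixture_spec(seed = 5, n_compounds = 8, n_targets = 5,
                        n_planted_targets = 2, ligands_per_target = 3,
                        noise_rate = 0, miss_rate = 0)
  lib <- generate_library(spec0)
  refs <- generate_reference_sets(spec0, lib)
  mats <- generate_method_noise(spec0, lib, refs$truth)
  truth_keys <- paste(refs$truth$compound_id, refs$truth$target_id)
  for (m in mats) {
    expect_setequal(paste(m$entries$compound_id, m$entries$target_id), truth_keys)
  }
  # distinct methods carry independent noise streams
  spec1 <- fixture_spec(seed = 5, n_compounds = 8, n_targets = 5,
                        n_planted_targets = 2, ligands_per_target = 3,
                        noise_rate = 0.5, miss_rate = 0.2)
  noisy <- generate_method_noise(spec1, lib, refs$truth)
  keys <- lapply(noisy, function(m) sort(paste(m$entries$compound_id, m$entries$target_id)))
  expect_false(identical(keys[[1]], keys[[2]]))
})
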