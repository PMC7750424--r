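test_that("generation is deterministic in the seed", {
  a <- generate_variants(generator_config(n_variants = 168, seed = 1))
  b <- generate_variants(generator_config(n_variants = 168, seed = 1))
  expect_identical(a$records, b$records)
  expect_identical(a$truth$latent, b$truth$latent)
  c <- generate_variants(generator_config(n_variants = 168, seed = 2))
  expect_false(identical(a$records$production_rate,
                         c$records$production_rate))
})

test_that("counts are non-negative integers centred on the base composition", {
  ds <- generate_variants(generator_config(n_variants = 2000, seed = 3))
  X <- as.matrix(ds$records[, aa_alphabet()])
  expect_true(all(X >= 0))
  expect_true(all(X == round(X)))
  base <- media_fixture()$demand
  realized <- colMeans(X)
  nz <- base > 0
  expect_true(all(abs(realized[nz] - base[nz]) / base[nz] < 0.05))
})

test_that("the noiseless limit makes labels a monotone function of the score", {
  ds <- generate_variants(generator_config(n_variants = 100, noise_sd = 0,
                                           seed = 6))
  ord <- order(ds$truth$latent)
  expect_true(all(diff(ds$records$label[ord]) >= 0))
})

test_that("realised class shares land near the configured proportions", {
  ds <- generate_variants(generator_config(n_variants = 500, seed = 10))
  shares <- as.numeric(table(factor(ds$records$label, levels = 0:2))) / 500
  expect_true(all(abs(shares - c(0.40, 0.40, 0.20)) <= 0.05))
  expect_error(generator_config(n_variants = 3,
                                proportions = c(0.99, 0.005, 0.005)),
               "large enough")
})

test_that("the dataset CSV round-trips with labels derived, never stored", {
  ds <- generate_variants(generator_config(n_variants = 40, seed = 12))
  tmp <- tempfile(fileext = ".csv")
  write_variants_csv(ds, tmp)
  header <- strsplit(readLines(tmp, n = 1), ",")[[1]]
  expect_false("label" %in% header)
  back <- read_variants_csv(tmp)
  expect_equal(back$label, ds$records$label)
  expect_equal(back[, aa_alphabet()], ds$records[, aa_alphabet()])
  expect_equal(back$production_rate, ds$records$production_rate,
               tolerance = 1e-12)
})

test_that("the signal-peptide fixture matches its pinned repertoire", {
  sp <- sp_fixture()
  expect_equal(nrow(sp), 14)
  expect_equal(sp$family, c(paste0("Vk", 1:6), paste0("VH", 1:7), "IgE"))
  expect_equal(nchar(sp$sequence[sp$family == "Vk1"]), 22)
  expect_equal(sp$sequence[sp$family == "VH1"],
               sp$sequence[sp$family == "VH7"])
  expect_equal(sp$chain[sp$family == "Vk3"], "light")
  expect_true(all(substr(sp$sequence, 1, 1) == "M"))
})

test_that("the media fixture carries the expected supply and demand", {
  med <- media_fixture()
  expect_equal(sort(names(med$supply[med$supply == 0])),
               c("A", "D", "E", "N", "P"))
  expect_equal(unname(med$demand["W"]), 25)
  expect_equal(unname(med$supply["Q"]), 24.07e20)
  expect_equal(sum(med$demand > 0), 20)
})

test_that("fixture files are immutable (checksums pinned)", {
  files <- c(sp_families.fasta = "98e5a10d72d8600087ceb8e0876e8e53",
             dmem_media.csv = "0bb090558a9be83f66a0e97902c1f18e",
             antibody_demand.csv = "92ee14372860f690edbab37e5650e566")
  for (f in names(files)) {
    path <- system.file("extdata", f, package = "aacap", mustWork = TRUE)
    expect_equal(unname(tools::md5sum(path)), unname(files[[f]]), label = f)
  }
})

test_that("end to end, the fitted model beats the baseline on fresh splits", {
  ds <- generate_variants(generator_config(seed = 14))  # default n = 168
  reps <- suppressWarnings(
    run_replicates(ds$records, n_replicates = 3, base_seed = 14,
                   lambda_grid = 10^seq(-4, 2, length.out = 4), folds = 10)
  )
  wins <- vapply(reps, function(r) {
    model_auc <- mean(c(r$reports$T_a$model$pairwise_auc,
                        r$reports$T_b$model$pairwise_auc))
    base_auc <- mean(c(r$reports$T_a$baseline$pairwise_auc,
                       r$reports$T_b$baseline$pairwise_auc))
    model_auc > base_auc
  }, logical(1))
  expect_gte(sum(wins), 2)
})
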