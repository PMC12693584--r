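# a deliberately tiny scenario so the whole pipeline runs in seconds:
# strong rescaling, one small chunk, reduced sample
tiny_scenario <- function(name = "toy", syn = selection_model("neutral"),
                          n_replicates = 1L) {
  base <- sim_config(sample_n = 40, purge_every = 25)
  scenario(name, syn_model = syn, n_replicates = n_replicates,
           rescale_Q = 50L, n_chunks = 1L, target_exonic = 2e5,
           base_config = base)
}

test_that("scenario grids cover the designed conditions", {
  sc <- constant_size_scenarios()
  expect_length(sc, 7)
  expect_equal(sc$control$config$syn_model$kind, "neutral")
  expect_equal(sc[["constant_1e-4"]]$config$syn_model$s, 1e-4 * 10)
  expect_equal(sc[["partial_1e-3"]]$config$syn_model$p, 0.22)
  # the two elevated recombination rates add 14 selection-by-r combinations
  hi <- constant_size_scenarios(r = c(1e-7, 1e-6))
  expect_length(hi, 14)
  expect_equal(unique(vapply(hi, function(s) s$config$r, 0)),
               c(1e-7, 1e-6) * 10)
})

test_that("run_scenario produces complete, reproducible replicate rows", {
  sc <- tiny_scenario(n_replicates = 2L)
  res <- run_scenario(sc, seed = 5, n_starts = 6)
  expect_equal(nrow(res), 2)
  expect_true(all(is.na(res$error)))
  expect_true(all(res$model %in% c("one_epoch", "two_epoch")))
  expect_true(all(is.finite(res$theta_s)))
  expect_true(all(is.finite(res$shape)))
  expect_s3_class(res$syn_sfs[[1]], "sfs")
  expect_s3_class(res$demog[[1]], "demog_fit")
  expect_s3_class(res$dfe[[1]], "dfe_fit")
  res2 <- run_scenario(sc, seed = 5, n_starts = 6)
  expect_equal(res$theta_s, res2$theta_s)
  expect_equal(res$shape, res2$shape)
  expect_equal(res$delta_ll, res2$delta_ll)
})

test_that("replicate failures are isolated, not fatal", {
  sc <- tiny_scenario(n_replicates = 2L)
  sc$config$sample_n <- 10 * sc$config$N  # sampling must fail
  res <- run_scenario(sc, seed = 2, n_starts = 4)
  expect_equal(nrow(res), 2)
  expect_true(all(!is.na(res$error)))
  expect_true(all(is.na(res$shape)))
})

test_that("self-pairing in the neutral swap reproduces the standard fit", {
  res <- run_scenario(tiny_scenario(n_replicates = 1L), seed = 9,
                      n_starts = 6)
  sw <- neutral_swap(res, res, n_starts = 6, seed = 9)
  expect_equal(sw$swap_shape, res$shape, tolerance = 1e-3)
  expect_equal(sw$swap_scale_gamma, res$scale_gamma, tolerance = 1e-2)
})

test_that("neutral swap validates sample-size compatibility", {
  res <- run_scenario(tiny_scenario(n_replicates = 1L), seed = 9,
                      n_starts = 4)
  other <- res
  other$ns_sfs[[1]] <- sfs(rep(1, 21))
  expect_error(neutral_swap(other, res, n_starts = 4), "sample-size")
})

test_that("report writes tables, spectra and figures", {
  res <- run_scenario(tiny_scenario(n_replicates = 1L), seed = 9,
                      n_starts = 4)
  out <- withr::local_tempdir()
  paths <- report_results(res, out)
  expect_true(file.exists(file.path(out, "results.csv")))
  expect_true(any(grepl("\\.fs$", paths)))
  expect_true(file.exists(file.path(out, "shape_scale.png")))
  tab <- readr::read_csv(file.path(out, "results.csv"),
                         show_col_types = FALSE)
  expect_equal(nrow(tab), 1)
  expect_warning(report_results(res[0, ], out), "nothing written")
})

test_that("tidy accessors expose the DFE fit", {
  res <- run_scenario(tiny_scenario(n_replicates = 1L), seed = 9,
                      n_starts = 4)
  td <- tidy(res$dfe[[1]])
  expect_setequal(td$term, c("shape", "scale_gamma", "scale_s_dhet"))
  expect_true(all(is.finite(glance(res$dfe[[1]])$loglik)))
})
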