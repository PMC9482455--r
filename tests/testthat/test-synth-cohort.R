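test_that("group configurations reproduce the study design", {
  cfg <- default_cohort_config()
  expect_named(cfg$groups, c("WT_young", "APP_KI_young", "WT_old", "APP_KI_old"))
  ns <- vapply(cfg$groups, `[[`, integer(1), "n")
  expect_equal(unname(ns), c(7L, 10L, 10L, 8L))
  expect_equal(cfg$groups$WT_young$sexes, c(M = 3L, F = 4L))
  # region means sum exactly to the group overall connectivity
  for (g in cfg$groups) {
    expect_equal(sum(g$regions$mu), g$overall, tolerance = 1e-12)
    expect_true(all(g$regions$mu >= 0))
    expect_true(all(g$regions$theta > 0))
  }
})

test_that("simulate_cohort returns the configured group with tagged sexes", {
  sim <- simulate_cohort(default_cohort_config(), "WT_young", seed = 3)
  expect_equal(nrow(sim$animals), 7)
  expect_equal(unique(sim$animals$genotype), "WT")
  expect_equal(unique(sim$animals$age_group), "young")
  expect_equal(sum(sim$animals$sex == "M"), 3)
  expect_equal(sum(sim$animals$sex == "F"), 4)
  expect_true(all(sim$animals$S >= 1))
  expect_true(all(sim$counts$count >= 0))
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- image_mode_config()
  a <- simulate_animal(cfg, "WT_young", "M", "d1", seed = 17, level = "cells")
  b <- simulate_animal(cfg, "WT_young", "M", "d1", seed = 17, level = "cells")
  expect_identical(a, b)
  c1 <- simulate_cohort(default_cohort_config(), "WT_old", seed = 5)
  c2 <- simulate_cohort(default_cohort_config(), "WT_old", seed = 5)
  expect_identical(c1, c2)
})

test_that("zero region means yield starter-only animals", {
  cfg <- tiny_cohort_config(mu = c(CA3_Py_ipsi = 0), starter_sdlog = 0)
  sim <- simulate_animal(cfg, "WT_young", "M", "z1", seed = 2, level = "cells")
  expect_equal(sim$animal$N_tot, 0)
  expect_true(all(sim$cells$class == "starter"))
  expect_equal(sum(sim$counts$count), 0)
})

test_that("near-infinite dispersion matches a Poisson oracle in mean and variance", {
  cfg <- tiny_cohort_config(mu = c(CA3_Py_ipsi = 2), theta = 1e4,
                            starter_sdlog = 0)  # S fixed at 150
  n <- 10000
  set.seed(21)
  seeds <- sample.int(2^31 - 2, n)
  draws <- vapply(seeds, function(s) {
    sim <- simulate_animal(cfg, "WT_young", "M", "p", seed = s)
    sim$counts$count[sim$counts$key == "CA3_Py_ipsi"]
  }, integer(1))
  set.seed(99)
  oracle <- rpois(n, 2 * 150)
  se_mean <- sqrt(var(oracle) / n + var(draws) / n)
  expect_lt(abs(mean(draws) - mean(oracle)), 3 * se_mean)
  # variance of Poisson(300): SE of sample variance ~ sqrt(2/(n-1)) * var
  se_var <- sqrt(2 / (n - 1)) * 300 * sqrt(2)
  expect_lt(abs(var(draws) - var(oracle)), 3 * se_var)
})

test_that("E[N_r]/E[S] recovers the configured mean CSI", {
  cfg <- tiny_cohort_config(mu = c(MS_DB = 1.5, CA3_Py_ipsi = 4), n = 40,
                            sexes = c(M = 20L, F = 20L))
  sims <- lapply(1:50, function(s) simulate_cohort(cfg, "WT_young", seed = s))
  for (key in c("MS_DB", "CA3_Py_ipsi")) {
    # per-cohort CSI (animal ids repeat across independent cohorts)
    csi <- unlist(lapply(sims, function(s) {
      ct <- s$counts[s$counts$key == key, ]
      ct$count / s$animals$S[match(ct$animal_id, s$animals$animal_id)]
    }))
    mu <- cfg$groups$WT_young$regions$mu[cfg$groups$WT_young$regions$key == key]
    expect_lt(abs(mean(csi) - mu), 3 * sd(csi) / sqrt(length(csi)))
  }
})

test_that("planted cell records aggregate exactly to the count table", {
  cfg <- image_mode_config()
  sim <- simulate_cohort(cfg, "WT_young", seed = 8, level = "cells")
  inputs <- sim$cells[sim$cells$class == "input", ]
  agg <- table(factor(inputs$key, levels = region_keys()), inputs$animal_id)
  for (id in sim$animals$animal_id) {
    ct <- sim$counts[sim$counts$animal_id == id, ]
    expect_equal(as.integer(agg[ct$key, id]), ct$count)
  }
  # starters restricted to ipsilateral CA1 pyramidal layer
  expect_true(all(sim$cells$key[sim$cells$class == "starter"] == "CA1_Py_ipsi"))
})

test_that("cell APs land on the mounted-section grid inside the region slab", {
  cfg <- image_mode_config()
  sim <- simulate_animal(cfg, "WT_young", "M", "g1", seed = 30, level = "cells")
  step <- cfg$section_step
  expect_true(all(abs(sim$cells$ap / step - round(sim$cells$ap / step)) < 1e-9))
  at <- load_atlas()
  for (i in seq_len(nrow(sim$cells))) {
    row <- at[at$region == sim$cells$code[i], ]
    expect_true(sim$cells$ap[i] >= row$ap_min && sim$cells$ap[i] <= row$ap_max)
  }
})

test_that("invalid configurations are rejected", {
  cfg <- default_cohort_config()
  cfg$groups$WT_young$regions$mu[1] <- -1
  expect_error(simulate_cohort(cfg, "WT_young", 1), "negative region mean")
  cfg2 <- default_cohort_config()
  cfg2$groups$WT_young$n <- 1L
  cfg2$groups$WT_young$sexes <- c(M = 1L, F = 0L)
  expect_error(simulate_cohort(cfg2, "WT_young", 1), "at least 2 animals")
  expect_error(simulate_cohort(default_cohort_config(), "nope", 1), "unknown group")
})

test_that("the sex multiplier preserves the group mean while planting a female deficit", {
  cfg <- tiny_cohort_config(mu = c(SUB_ipsi = 2), n = 8,
                            sexes = c(M = 5L, F = 3L),
                            sex_mult = list(SUB_ipsi = 0.55),
                            starter_sdlog = 0)
  mu_f <- rabiestrace:::sex_adjusted_mu(cfg$groups$WT_young, "F")["SUB_ipsi"]
  mu_m <- rabiestrace:::sex_adjusted_mu(cfg$groups$WT_young, "M")["SUB_ipsi"]
  expect_lt(mu_f, mu_m)
  expect_equal(unname(5 * mu_m + 3 * mu_f) / 8, 2)
})

test_that("cohorts round-trip through CSV with the seed recorded", {
  sim <- simulate_cohort(image_mode_config(), "WT_young", seed = 4, level = "cells")
  dir <- withr::local_tempdir()
  write_cohort(sim, dir, seed = 4)
  expect_match(readLines(file.path(dir, "animals.csv"), n = 1), "seed=4")
  back <- read_cohort(dir)
  expect_equal(back$animals$S, sim$animals$S)
  expect_equal(back$counts$count, sim$counts$count)
  expect_equal(nrow(back$cells), nrow(sim$cells))
})
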