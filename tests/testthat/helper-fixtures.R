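# shared fixtures: small cohort configs and brute-force oracles

# minimal single-group cohort config with chosen region means/dispersion
tiny_cohort_config <- function(mu = c(CA3_Py_ipsi = 2), theta = 8, n = 3,
                               sexes = c(M = 2L, F = 1L), group = "WT_young",
                               starter_mean = 150, starter_sdlog = 0.25,
                               helper_frac = 0, sex_mult = list()) {
  keys <- region_keys()
  muv <- stats::setNames(rep(0, length(keys)), keys)
  muv[names(mu)] <- mu
  regions <- data.frame(key = keys, mu = unname(muv), theta = theta,
                        source = "test", stringsAsFactors = FALSE)
  cfg <- default_cohort_config()
  cfg$groups <- list(list(name = group, genotype = "WT", age_group = "young",
                          n = n, sexes = sexes, overall = sum(muv),
                          regions = regions, sex_mult = sex_mult))
  names(cfg$groups) <- group
  cfg$starter <- list(mean = starter_mean, sdlog = starter_sdlog)
  cfg$helper_frac <- helper_frac
  cfg
}

# reduced-size study config suitable for cell-level / image-mode runs:
# sparse enough that rendered spots never overlap
image_mode_config <- function(groups = "WT_young") {
  scale_cohort_config(default_cohort_config(), mu_scale = 0.03,
                      starter_mean = 12, min_spacing = 80,
                      helper_frac = 0.2, groups = groups)
}

# brute-force two-sided rank-sum p by full enumeration of group assignments
oracle_rank_sum_p <- function(x, y) {
  n <- length(x)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)])
  ws <- apply(utils::combn(length(r), n), 2, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(ws <= W), mean(ws >= W)))
}

# brute-force two-sided signed-rank p by enumerating all 2^n sign patterns
oracle_signed_rank_p <- function(a, b) {
  d <- (a - b)
  d <- d[d != 0]
  if (!length(d)) return(1)
  r <- rank(abs(d))
  Wp <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
  ws <- as.vector(signs %*% r)
  min(1, 2 * min(mean(ws <= Wp), mean(ws >= Wp)))
}

# per-animal metric vectors from a simulated cohort, for one region key
cohort_metric <- function(sim, key, metric = c("csi", "pi")) {
  metric <- match.arg(metric)
  conn <- connectivity_table(sim$animals, sim$counts)
  conn[[metric]][conn$key == key]
}
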