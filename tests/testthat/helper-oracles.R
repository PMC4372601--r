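# Independent brute-force oracles. Each re-derives a pipeline quantity with
# straight-line code that shares nothing with the package implementation.

# Straight-line per-array normalization: sort/trim blanks, explicit mean/SD,
# strict threshold, background subtraction, median rescaling.
oracle_normalize <- function(scan, trim = 0.05, mult = 2, target = 25) {
  blanks <- scan$spots$intensity[scan$spots$spot_class == "blank"]
  srt <- sort(blanks)
  k <- floor(trim * length(srt))
  kept <- srt[(k + 1):(length(srt) - k)]
  m <- sum(kept) / length(kept)
  s <- sqrt(sum((kept - m)^2) / (length(kept) - 1))
  thr <- m + mult * s
  probes <- scan$spots[scan$spots$spot_class == "probe", ]
  present <- probes$intensity > thr
  corrected <- probes$intensity[present] - m
  cs <- sort(corrected)
  n <- length(cs)
  med <- if (n %% 2 == 1) cs[(n + 1) / 2] else (cs[n / 2] + cs[n / 2 + 1]) / 2
  vals <- rep(0, nrow(probes))
  vals[present] <- corrected * target / med
  names(vals) <- probes$probe_id
  list(values = vals, present = stats::setNames(present, probes$probe_id),
       threshold = thr, mean = m, sd = s)
}

# Mann-Whitney U by direct pair counting, p by full enumeration of group
# labelings; two-sided as the tail probability of |U - n1*n2/2|.
oracle_mwu <- function(a, b) {
  na <- length(a); nb <- length(b)
  count_u <- function(x, y) {
    u <- 0
    for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
    u
  }
  u_obs <- count_u(a, b)
  pooled <- c(a, b)
  idx <- utils::combn(na + nb, na)
  center <- na * nb / 2
  extreme <- 0
  for (j in seq_len(ncol(idx))) {
    u_j <- count_u(pooled[idx[, j]], pooled[-idx[, j]])
    if (abs(u_j - center) >= abs(u_obs - center) - 1e-9) extreme <- extreme + 1
  }
  list(u = u_obs, p_value = extreme / ncol(idx))
}

# Lexicographic permutation generation (distinct from the package's
# block-prepend construction).
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oracle_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    out <- rbind(out, cbind(first, matrix(rest[sub], nrow(sub))))
  }
  out
}

# Spearman rho from the explicit Pearson-on-midranks formula; exact p over
# all permutations of y.
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- (sum(v < v[i]) + 1 + sum(v <= v[i])) / 2
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  pear <- function(u, v) {
    sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  rho_obs <- pear(rx, ry)
  perms <- oracle_perms(length(y))
  hits <- 0
  for (j in seq_len(nrow(perms))) {
    if (abs(pear(rx, ry[perms[j, ]])) >= abs(rho_obs) - 1e-12) hits <- hits + 1
  }
  list(rho = rho_obs, p_value = hits / nrow(perms))
}

# Random small scan: n_probe expressed probes over a blank background.
make_scan <- function(n_probe = 8, n_blank = 25, sample_id = "S1",
                      group = "FM", probe_level = NULL) {
  blanks <- rlnorm(n_blank, log(30), 0.4)
  level <- probe_level %||% rlnorm(n_probe, log(400), 1)
  spots <- data.frame(
    probe_id = c(sprintf("mir-%03d", seq_len(n_probe)),
                 sprintf("blank-%03d", seq_len(n_blank))),
    spot_class = c(rep("probe", n_probe), rep("blank", n_blank)),
    intensity = c(level + rlnorm(n_probe, log(30), 0.4), blanks))
  array_scan(sample_id, group, spots)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small expression matrix from explicit per-group value vectors.
make_matrix <- function(control, fm, mirna_ids = NULL) {
  control <- as.matrix(control); fm <- as.matrix(fm)
  values <- cbind(control, fm)
  colnames(values) <- c(paste0("C", seq_len(ncol(control))),
                        paste0("FM", seq_len(ncol(fm))))
  rownames(values) <- mirna_ids %||% sprintf("mir-%03d", seq_len(nrow(values)))
  groups <- stats::setNames(rep(c("control", "FM"), c(ncol(control), ncol(fm))),
                            colnames(values))
  expression_matrix(values, groups)
}

# Small-cohort config used where full study scale is unnecessary. Broad
# downregulation is off by default because a 40-probe array has too few
# abundant probes to host it.
small_config <- function(..., seed = 1) {
  args <- list(n_mirna = 40, n_blank = 25, broad_down_fraction = 0, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(simulation_config, args)
}
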