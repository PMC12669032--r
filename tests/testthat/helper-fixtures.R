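# shared in-code fixtures

# minimal 96-well plate map: 88 treatments, 8 vehicle controls
makePlateMap <- function(plate_id = "P1", n_dmso = 8L) {
  all_wells <- as.vector(outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0))
  dmso <- all_wells[seq(1L, 96L, length.out = n_dmso)]
  treat <- setdiff(all_wells, dmso)
  PlateMap(plate_id,
           c(treat, dmso),
           c(sprintf("cmpd%03d", seq_along(treat)), rep("DMSO", n_dmso)),
           c(rep(20, length(treat)), rep(0, n_dmso)),
           c(rep("treatment", length(treat)), rep("vehicle_control", n_dmso)))
}

# small curve set: n wells on an hourly 0..24 h grid, logistic + optional noise
makeCurves <- function(n = 3L, K = 1, r = 0.5, n0 = 0.05, cv = 0, seed = 1L) {
  set.seed(seed)
  times <- 0:24
  base <- K / (1 + ((K - n0) / n0) * exp(-r * times))
  od <- matrix(rep(base, each = n), n)
  if (cv > 0) {
    s <- sqrt(log(1 + cv^2))
    od <- od * matrix(rlnorm(length(od), -s^2 / 2, s), n)
  }
  GrowthCurveSet(times, od,
                 S4Vectors::DataFrame(plate_id = "P1",
                                      well = sprintf("A%02d", seq_len(n)),
                                      strain_id = "s1", replicate = 1L))
}

# independent Welch t-test oracle (textbook formula)
welchOracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(t), df)
}

# independent BH step-up oracle with explicit m
bhOracle <- function(p, m = length(p)) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}
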