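# Shared fixtures: reporter layouts, models and an independently constructed
# three-colour class table whose class frequencies are exact by design.

two_marker_layout <- function(modality = "tetrad", L = 1e6) {
  reporter_layout(data.frame(name = c("G", "R"), pos_bp = c(1, L),
                             colour = c("G", "R")), modality)
}

# B-Y-R triple spanning the whole chromosome; the Y marker splits the map
# into intervals of d_b and d_c Morgans
three_marker_layout <- function(modality = "pollen3", d_b = 0.2, d_c = 0.11,
                                L = 4.4e6) {
  reporter_layout(data.frame(
    name = c("CFP", "YFP", "dsRed"),
    pos_bp = c(1, round(L * d_b / (d_b + d_c)), L),
    colour = c("B", "Y", "R")), modality)
}

three_marker_model <- function(nu = 1, d_b = 0.2, d_c = 0.11, L = 4.4e6,
                               seed = NULL, escape_fraction = 0) {
  sim_model(L, map_length_morgans = d_b + d_c, nu = nu,
            escape_fraction = escape_fraction, rng_seed = seed)
}

# Constructed eight-class table: interval b recombinants 2000/10000 (20 cM),
# interval c 1100/10000 (11 cM), observed DCO = 220 = expected under
# independence, so CoC is exactly 1.
constructed_threecolour <- function() {
  threecolour_counts(c(BYR = 3560, `BY-` = 440, `B-R` = 110, `B--` = 890,
                       `-YR` = 890, `-Y-` = 110, `--R` = 440, `---` = 3560))
}

# brute-force Benjamini-Hochberg step-up written from the definition:
# adjusted p for rank i = min over j >= i of p_(j) * m / j, capped at 1
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# expected selfed-seed class counts (real-valued) at recombinant fraction r
expected_seed_counts <- function(r, N) {
  q <- (1 - r) / 2
  seed_counts(N_GR = (0.5 + q^2) * N, N_G = (0.25 - q^2) * N,
              N_R = (0.25 - q^2) * N, N_N = q^2 * N)
}
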