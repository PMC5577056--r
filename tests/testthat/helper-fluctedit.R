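# shared test fixtures, all built in code

# a synthetic "fully extended" tripeptide: residues spaced far enough apart
# that the central residue is almost completely solvent-exposed
extended_tripeptide_pdb <- function(path, spacing = 7) {
  atoms <- data.frame(chain = "A", residue = rep(1:3, each = 5),
                      atom = rep(c("N", "CA", "C", "O", "CB"), 3),
                      aa = rep("LEU", 15))
  xyz <- matrix(0, 15, 3)
  off <- rbind(c(-1.2, 0.8, 0), c(0, 0, 0), c(1.2, 0.6, 0),
               c(1.5, 1.7, 0), c(0, -1.4, 0.8))
  for (i in 1:3)
    xyz[(i - 1) * 5 + 1:5, ] <- sweep(off, 2, c((i - 1) * spacing, 0, 0), `+`)
  ens <- snapshot_ensemble(atoms, array(rep(xyz, 2), c(15, 3, 2)))
  write_ensemble_pdb(ens, path)
  path
}

# a residue whose atoms sit at the centre of a close-packed shell of atoms:
# construction guarantees burial
buried_residue_pdb <- function(path, seed = 1) {
  set.seed(seed)
  n <- 60
  shell <- matrix(rnorm(n * 3), n, 3)
  shell <- shell / sqrt(rowSums(shell^2)) * runif(n, 4.5, 7)
  atoms <- data.frame(chain = "A",
                      residue = c(rep(1, 5), rep(2:13, each = 5)),
                      atom = rep(c("N", "CA", "C", "O", "CB"), 13),
                      aa = "LEU")
  off <- rbind(c(-1.2, 0.8, 0), c(0, 0, 0), c(1.2, 0.6, 0),
               c(1.5, 1.7, 0), c(0, -1.4, 0.8))
  xyz <- rbind(off, shell)
  ens <- snapshot_ensemble(atoms, array(rep(xyz, 2), c(65, 3, 2)))
  write_ensemble_pdb(ens, path)
  path
}

# independent brute-force enumeration of the selection predicate
brute_force_select <- function(ann, asa_threshold = 20) {
  out <- character(0)
  for (i in seq_len(nrow(ann))) {
    if (ann$has_dispersion[i] && !ann$in_cdr[i] &&
        !(ann$aa[i] %in% c("A", "G", "S", "T", "V")) &&
        ann$relative_asa[i] > asa_threshold)
      out <- c(out, ann$residue_id[i])
  }
  sort(out)
}

# exhaustive two-sided Mann-Whitney p-value by enumerating all rank
# assignments (no ties assumed)
enumerate_rank_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2  # U statistic for a
  combs <- utils::combn(length(pooled), na)
  u_all <- apply(combs, 2, function(ix)
    sum(rank(pooled)[ix]) - na * (na + 1) / 2)
  mu <- na * length(b) / 2
  mean(abs(u_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# noiseless single-residue fast-exchange curves at two fields
noiseless_lm_curves <- function(k_ex = 1500, phi_ppm2 = 0.05,
                                r2_0 = c(14, 16),
                                fields = c(600.13, 750.13)) {
  nu <- c(25, 50, 75, 100, 150, 200, 300, 400, 500, 650, 800, 1000)
  rows <- lapply(seq_along(fields), function(i) {
    f <- field_context(fields[i])
    data.frame(chain = "H", residue = 71, aa = "R", field_mhz = fields[i],
               nu_cpmg = nu,
               r2eff = luz_meiboom_r2eff(
                 nu, exchange_params(r2_0[i], k_ex, phi_ppm2 = phi_ppm2), f),
               sigma = 0.3)
  })
  dispersion_data(do.call(rbind, rows))
}
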