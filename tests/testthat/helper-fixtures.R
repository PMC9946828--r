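# shared fixture builders; everything generated in code, no stored data

# a minimal 3-residue PDB text, complete backbone
fixture_pdb_lines <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00",
    "ATOM      4  N   GLY A   2       3.332   1.536   0.000  1.00  0.00",
    "ATOM      5  CA  GLY A   2       4.040   2.790   0.200  1.00  0.00",
    "ATOM      6  C   GLY A   2       5.480   2.500   0.600  1.00  0.00",
    "ATOM      7  N   SER A   3       6.300   3.540   0.700  1.00  0.00",
    "ATOM      8  CA  SER A   3       7.730   3.400   1.000  1.00  0.00",
    "ATOM      9  C   SER A   3       8.400   4.740   1.300  1.00  0.00",
    "END")
}

write_fixture_pdb <- function(path = tempfile(fileext = ".pdb"),
                              lines = fixture_pdb_lines()) {
  writeLines(lines, path)
  path
}

# ideal alpha-helix backbone of n residues
helix_backbone <- function(n = 12, sequence = NULL) {
  tors <- matrix(rep(c(-57, -47, 180), n), ncol = 3, byrow = TRUE,
                 dimnames = list(NULL, c("phi", "psi", "omega")))
  build_backbone_from_torsions(tors, sequence = sequence)
}

# independent dihedral oracle: explicit cross-product formula, coded
# separately from the package implementation (atan2 on projections)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(u, v) c(u[2]*v[3] - u[3]*v[2],
                            u[3]*v[1] - u[1]*v[3],
                            u[1]*v[2] - u[2]*v[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cross(n1, n2) * b2) / sqrt(sum(b2 * b2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# independent linear-search binning oracle over explicit edges
oracle_bin <- function(value, edges, no_contact_cutoff = NULL, seam_last = FALSE) {
  k <- length(edges)  # value bins = k - 1, plus trailing no-contact bin = k
  if (!is.null(no_contact_cutoff) && value >= no_contact_cutoff) return(k)
  if (seam_last && abs(value - edges[k]) < 1e-12) return(k - 1)
  for (b in seq_len(k - 1)) {
    if (value >= edges[b] && value < edges[b + 1]) return(b)
  }
  if (value < edges[1]) return(1L)
  k - 1L
}

# small rigid-body transform helpers
rotate_backbone <- function(bb, axis = c(1, 1, 1), angle = 0.7, shift = c(3, -2, 5)) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  for (at in names(bb$coords)) {
    ok <- stats::complete.cases(bb$coords[[at]])
    bb$coords[[at]][ok, ] <- sweep(bb$coords[[at]][ok, , drop = FALSE] %*% t(R),
                                   2, -shift)
  }
  bb
}

mirror_backbone <- function(bb) {
  for (at in names(bb$coords)) bb$coords[[at]][, 3] <- -bb$coords[[at]][, 3]
  bb
}

# tiny degenerate planted problem shared by mcmc tests (cheap to build)
small_planted <- function(n_random = 100, seed = 5) {
  spec <- toy_family_spec(
    n_members = 3,
    segment_plan = list(list(type = "helix", length = 5),
                        list(type = "loop", length = c(2, 2)),
                        list(type = "strand", length = 5)),
    coordinate_jitter = 0,
    planted_sequence = "ADKLMWERHI")
  make_planted_problem(spec, seed = seed, n_random = n_random)
}
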