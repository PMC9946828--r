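# Standard peptide internal coordinates used by the chain builder (trans
# peptide, ideal geometry). All lengths in Angstrom, angles in degrees.
PEPTIDE_GEOMETRY <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.1
)

# canonical torsions per secondary-structure type
SEGMENT_TORSIONS <- list(
  helix = c(phi = -57, psi = -47, omega = 180),
  strand = c(phi = -139, psi = 135, omega = 180),
  loop = c(phi = -70, psi = 140, omega = 180)
)

#' Build a backbone from phi/psi/omega torsions
#'
#' Sequential internal-to-Cartesian chain extension with standard bond lengths
#' and angles (N-CA 1.458 A, CA-C 1.525 A, C-N 1.329 A). Residue k's `phi`
#' sets the C(k-1)-N(k)-CA(k)-C(k) torsion, `psi` the N-CA-C-N(k+1) torsion
#' and `omega` the CA(k-1)-C(k-1)-N(k)-CA(k) peptide torsion (so `phi` of the
#' first and `omega` of the first residue are unused). Carbonyl O atoms are
#' placed trans to the following N; C-beta atoms are added with
#' [reconstruct_cb()] (glycines excepted).
#'
#' @param torsions matrix or data frame with columns `phi`, `psi`, `omega`
#'   (degrees), one row per residue (>= 2 rows).
#' @param sequence optional 1-letter amino-acid string naming the residues
#'   (default poly-alanine).
#' @param chain_id chain identifier.
#' @return a `backbone` with N/CA/C/O (and CB) coordinates; the first residue
#'   sits in a canonical frame at the origin.
#' @export
build_backbone_from_torsions <- function(torsions, sequence = NULL,
                                         chain_id = "A") {
  torsions <- as.matrix(as.data.frame(torsions)[, c("phi", "psi", "omega")])
  n <- nrow(torsions)
  if (n < 2) stop("need at least 2 residues", call. = FALSE)
  if (any(!is.finite(torsions))) stop("non-finite torsion angle", call. = FALSE)
  g <- PEPTIDE_GEOMETRY
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N
  # canonical first-residue frame
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$ca_c * c(-cos(ang), sin(ang), 0)
  for (k in 2:n) {
    N[k, ] <- place_atom(N[k - 1, ], CA[k - 1, ], C[k - 1, ],
                         g$c_n, g$ang_ca_c_n, torsions[k - 1, "psi"])
    CA[k, ] <- place_atom(CA[k - 1, ], C[k - 1, ], N[k, ],
                          g$n_ca, g$ang_c_n_ca, torsions[k, "omega"])
    C[k, ] <- place_atom(C[k - 1, ], N[k, ], CA[k, ],
                         g$ca_c, g$ang_n_ca_c, torsions[k, "phi"])
  }
  for (k in seq_len(n)) {
    # O trans to the next N (psi + 180); the last residue uses its own psi
    O[k, ] <- place_atom(N[k, ], CA[k, ], C[k, ],
                         g$c_o, g$ang_ca_c_o, torsions[k, "psi"] + 180)
  }
  resid <- if (is.null(sequence)) rep("ALA", n) else {
    aa <- strsplit(sequence, "")[[1]]
    if (length(aa) != n) stop("sequence length != torsion rows", call. = FALSE)
    unname(AA1_TO_3[aa])
  }
  bb <- backbone(resid, seq_len(n), list(N = N, CA = CA, C = C, O = O),
                 chain_id = chain_id)
  bb <- reconstruct_cb(bb)
  bb$coords$CB[bb$resid == "GLY", ] <- NA_real_
  bb
}

#' Specification of a synthetic toy protein family
#'
#' Describes a family of backbones sharing conserved secondary-structure
#' segments (helix/strand) with variable-length loops — the desk-scale
#' emulation of an experimental structure family used to exercise profile
#' building and hallucination without any download.
#'
#' @param n_members number of family members.
#' @param segment_plan ordered list of `list(type =, length =)` entries;
#'   `type` in helix/strand/loop; conserved (helix/strand) lengths are
#'   scalars, loop lengths may be a `c(min, max)` range sampled per member.
#' @param coordinate_jitter Gaussian coordinate noise s.d. in Angstrom applied
#'   to every member's atoms.
#' @param loop_length_seed,jitter_seed RNG seeds for the two sources of
#'   randomness.
#' @param planted_sequence optional amino-acid string for the conserved
#'   segments (length = total conserved residues), shared by all members;
#'   required by [make_planted_problem()].
#' @param kappa surrogate sharpness used by [make_planted_problem()].
#' @return an object of class `toy_family_spec`.
#' @export
toy_family_spec <- function(n_members = 6,
                            segment_plan = list(
                              list(type = "helix", length = 10),
                              list(type = "loop", length = c(2, 4)),
                              list(type = "strand", length = 8)),
                            coordinate_jitter = 0.05,
                            loop_length_seed = 11, jitter_seed = 12,
                            planted_sequence = NULL, kappa = 3) {
  types <- vapply(segment_plan, `[[`, character(1), "type")
  if (!any(types %in% c("helix", "strand"))) {
    stop("need at least one conserved (helix/strand) segment", call. = FALSE)
  }
  stopifnot(coordinate_jitter >= 0, n_members >= 1)
  cons_len <- sum(vapply(segment_plan[types != "loop"], `[[`, numeric(1), "length"))
  if (!is.null(planted_sequence) && nchar(planted_sequence) != cons_len) {
    stop(sprintf("planted_sequence must cover the %d conserved residues", cons_len),
         call. = FALSE)
  }
  structure(list(n_members = n_members, segment_plan = segment_plan,
                 coordinate_jitter = coordinate_jitter,
                 loop_length_seed = loop_length_seed, jitter_seed = jitter_seed,
                 planted_sequence = planted_sequence, kappa = kappa,
                 conserved_length = cons_len),
            class = "toy_family_spec")
}

#' Generate a synthetic toy family
#'
#' Members share the conserved helix/strand segments (with jittered
#' coordinates) and differ in loop lengths drawn per member from the plan's
#' ranges. The emitted alignment places loop residues left-aligned in a block
#' as wide as the longest possible loop, so its gap pattern encodes exactly
#' the constructed loop lengths. The truth annotation labels loop columns
#' variable by construction (independent of any gap-fraction threshold).
#'
#' @param spec a `toy_family_spec`.
#' @return list with `structures` (list of `backbone`), `alignment` (named
#'   character vector), `truth` (a `region_annotation`), `loop_lengths`
#'   (member x loop matrix) and `sequences`.
#' @export
make_toy_family <- function(spec) {
  stopifnot(inherits(spec, "toy_family_spec"))
  plan <- spec$segment_plan
  types <- vapply(plan, `[[`, character(1), "type")
  loop_idx <- which(types == "loop")
  # per-member loop lengths
  ll <- with_rng_seed(spec$loop_length_seed, {
    m <- matrix(0L, spec$n_members, length(loop_idx))
    for (j in seq_along(loop_idx)) {
      rng <- plan[[loop_idx[j]]]$length
      lo <- rng[1]; hi <- rng[length(rng)]
      m[, j] <- if (lo == hi) rep(as.integer(lo), spec$n_members) else
        sample(lo:hi, spec$n_members, replace = TRUE)
    }
    m
  })
  # conserved residue letters, shared across members
  cons_aa <- if (!is.null(spec$planted_sequence)) {
    strsplit(spec$planted_sequence, "")[[1]]
  } else {
    with_rng_seed(spec$loop_length_seed + 1L,
                  sample(DEFAULT_ALPHABET, spec$conserved_length, replace = TRUE))
  }
  structures <- vector("list", spec$n_members)
  aligned <- character(spec$n_members)
  sequences <- character(spec$n_members)
  col_class <- character(0)
  with_rng_seed(spec$jitter_seed, {
    for (m in seq_len(spec$n_members)) {
      tors <- NULL; aa <- character(0); arow <- character(0)
      ci <- 0L; lj <- 0L
      if (m == 1) col_class <- character(0)
      for (s in seq_along(plan)) {
        if (types[s] == "loop") {
          lj <- lj + 1L
          len <- ll[m, lj]
          width <- max(plan[[s]]$length)
          res <- if (len > 0) sample(DEFAULT_ALPHABET, len, replace = TRUE)
                 else character(0)
          arow <- c(arow, res, rep("-", width - len))
          aa <- c(aa, res)
          if (len > 0) {
            tors <- rbind(tors, matrix(rep(SEGMENT_TORSIONS$loop, len),
                                       ncol = 3, byrow = TRUE,
                                       dimnames = list(NULL, c("phi", "psi", "omega"))))
          }
          if (m == 1) col_class <- c(col_class, rep("variable", width))
        } else {
          len <- plan[[s]]$length
          res <- cons_aa[ci + seq_len(len)]
          ci <- ci + len
          arow <- c(arow, res)
          aa <- c(aa, res)
          tors <- rbind(tors, matrix(rep(SEGMENT_TORSIONS[[types[s]]], len),
                                     ncol = 3, byrow = TRUE,
                                     dimnames = list(NULL, c("phi", "psi", "omega"))))
          if (m == 1) col_class <- c(col_class, rep("conserved", len))
        }
      }
      seqstr <- paste(aa, collapse = "")
      bb <- build_backbone_from_torsions(tors, sequence = seqstr)
      if (spec$coordinate_jitter > 0) {
        for (at in names(bb$coords)) {
          ok <- stats::complete.cases(bb$coords[[at]])
          bb$coords[[at]][ok, ] <- bb$coords[[at]][ok, ] +
            stats::rnorm(sum(ok) * 3, sd = spec$coordinate_jitter)
        }
      }
      structures[[m]] <- bb
      aligned[m] <- paste(arow, collapse = "")
      sequences[m] <- seqstr
    }
  })
  names(aligned) <- sprintf("member%02d", seq_len(spec$n_members))
  mat <- do.call(rbind, strsplit(aligned, ""))
  truth <- build_annotation(mat, col_class == "conserved")
  list(structures = structures, alignment = aligned, truth = truth,
       loop_lengths = ll, sequences = sequences)
}

#' Bundle a planted-optimum hallucination problem
#'
#' Builds a toy family, its family profile, a surrogate predictor whose
#' compatibility weights peak at the spec's planted conserved-region sequence
#' (+1 for the planted residue, -1 otherwise, loops unscored), a background,
#' and a random start sequence. At construction the planted sequence is
#' verified to attain a lower total loss than every one of `n_random` random
#' sequences of the same length.
#'
#' @param spec a `toy_family_spec` with a `planted_sequence`.
#' @param seed seed for the background, start sequence and verification draws.
#' @param n_random number of random sequences for the construction check.
#' @return an object of class `planted_problem`: list with `profile`,
#'   `background`, `predictor`, `start_sequence`, `start_loop_lengths`,
#'   `planted_sequence` (conserved region), `planted_full` (with member-1
#'   loops), `family`, `cfg`.
#' @export
make_planted_problem <- function(spec, seed = 101, n_random = 1000) {
  stopifnot(inherits(spec, "toy_family_spec"))
  if (is.null(spec$planted_sequence)) {
    stop("spec has no planted_sequence", call. = FALSE)
  }
  fam <- make_toy_family(spec)
  bins <- bin_spec()
  # unsmoothed profile: with geometrically identical members the restraints
  # are exact one-hots, making the total loss strictly decreasing in the
  # surrogate confidence s and the planted sequence its unique argmin (any
  # restraint mass off the template bin shifts the optimum to interior s)
  profile <- build_profile(fam$structures, fam$alignment, fam$truth, bins,
                           pseudocount = 0)
  template <- compute_geometry(reconstruct_cb(fam$structures[[1]]), bins)
  tmap <- fam$truth$member_maps[[1]]
  cons_tpos <- tmap[fam$truth$conserved_cols]
  W <- matrix(NA_real_, template$length, length(DEFAULT_ALPHABET))
  planted <- strsplit(spec$planted_sequence, "")[[1]]
  for (k in seq_along(cons_tpos)) {
    W[cons_tpos[k], ] <- -1
    W[cons_tpos[k], match(planted[k], DEFAULT_ALPHABET)] <- 1
  }
  predictor <- make_surrogate(profile, template, W, kappa = spec$kappa)
  background <- compute_background(predictor, template$length,
                                   n_sequences = 100, seed = seed)
  cfg <- loss_config()
  start_loops <- loop_lengths_of_member(fam$truth, 1)
  L <- spec$conserved_length + sum(start_loops)
  bk <- layout_positions(fam$truth, start_loops)
  planted_full <- character(L)
  planted_full[!is.na(bk$column_map)] <- planted
  member1_aa <- strsplit(fam$sequences[1], "")[[1]]
  planted_full[is.na(bk$column_map)] <- member1_aa[is.na(bk$column_map)]
  planted_full <- paste(planted_full, collapse = "")

  score <- function(s) {
    pred <- predict_geometry(predictor, s, loop_lengths = start_loops)
    total_loss(pred, profile, background, bk$column_map, cfg)$total
  }
  planted_loss <- score(planted_full)
  start_sequence <- with_rng_seed(seed + 1L, {
    rand_losses <- vapply(seq_len(n_random), function(r) {
      score(paste(sample(DEFAULT_ALPHABET, L, replace = TRUE), collapse = ""))
    }, numeric(1))
    if (planted_loss >= min(rand_losses)) {
      stop(sprintf("planted optimum verification failed: planted %.4f >= best random %.4f",
                   planted_loss, min(rand_losses)), call. = FALSE)
    }
    paste(sample(DEFAULT_ALPHABET, L, replace = TRUE), collapse = "")
  })
  structure(list(profile = profile, background = background,
                 predictor = predictor, start_sequence = start_sequence,
                 start_loop_lengths = start_loops,
                 planted_sequence = spec$planted_sequence,
                 planted_full = planted_full, planted_loss = planted_loss,
                 family = fam, cfg = cfg, spec = spec),
            class = "planted_problem")
}

#' @export
print.planted_problem <- function(x, ...) {
  cat(sprintf("<planted_problem> planted %s (total loss %.4f), start %s\n",
              x$planted_sequence, x$planted_loss, x$start_sequence))
  invisible(x)
}

#' Reference planted-recovery problem specification
#'
#' The canonical desk-scale parameter-recovery experiment: a planted 18-mer
#' conserved sequence (a 9-residue helix and a 9-residue strand joined by one
#' 3-residue variable loop), a geometrically degenerate 6-member family
#' (jitter 0, equal loop lengths) so the unsmoothed profile is one-hot and
#' the planted sequence is the unique optimum of the total loss, and
#' surrogate sharpness kappa = 3.
#'
#' @return a `toy_family_spec`.
#' @export
planted_18mer_spec <- function() {
  toy_family_spec(
    n_members = 6,
    segment_plan = list(list(type = "helix", length = 9),
                        list(type = "loop", length = c(3, 3)),
                        list(type = "strand", length = 9)),
    coordinate_jitter = 0,
    planted_sequence = "ADKLMQWERHITNVGSPY",
    kappa = 3)
}

#' Conserved-region sequence of a state
#'
#' The residues at conserved positions in alignment-column order — the part of
#' a hallucinated sequence a planted-recovery experiment compares.
#' @param state a `hallucination_state`.
#' @return amino-acid string over the conserved positions.
#' @export
conserved_sequence <- function(state) {
  paste(state$sequence[!is.na(state$column_map)], collapse = "")
}

# fixed, synthetic 117-residue sequence (arginine at position 65); generated
# once with a seeded draw over a globular amino-acid composition
SYNTHETIC_DESIGN_SEQUENCE <- paste0(
  "MKTAYELVKQ", "AGLDLSNEFV", "IKGAHTDLSE", "VMRYFGEKAP",
  "DLINSAETGV", "KWLDTSNVLA", "EHGLRPEFTK", "IDVSGKAYEN",
  "AVFLNGQTVS", "EMWDKLAHPA", "YRTVFELGNK", "DSIVTGE")

#' Generate the synthetic design-model fixture
#'
#' A programmatically built stand-in for a small de novo luciferase design
#' model: a 117-residue single-chain backbone (helices and strands joined by
#' short loops), an arginine at position 65 whose guanidinium CZ atom is
#' modelled explicitly, and a minimal DTZ ligand hetero group whose N1 atom is
#' placed 4.2 A from that CZ. It exists to exercise the inspection utilities
#' ([residue_count()], [chain_mass()], [atom_distance()]) end to end; it is a
#' synthetic object, not a published design model.
#'
#' @param path optional path; when given the model is also written as PDB.
#' @return a `backbone` with 117 residues and a DTZ hetero group.
#' @export
make_synthetic_design_model <- function(path = NULL) {
  seq117 <- SYNTHETIC_DESIGN_SEQUENCE
  stopifnot(nchar(seq117) == 117, substr(seq117, 65, 65) == "R")
  plan <- list(c("helix", 14), c("loop", 4), c("strand", 9), c("loop", 3),
               c("strand", 10), c("loop", 4), c("helix", 12), c("loop", 3),
               c("strand", 9), c("loop", 4), c("strand", 10), c("loop", 3),
               c("helix", 13), c("loop", 4), c("strand", 15))
  tors <- do.call(rbind, lapply(plan, function(p) {
    matrix(rep(SEGMENT_TORSIONS[[p[1]]], as.integer(p[2])), ncol = 3,
           byrow = TRUE, dimnames = list(NULL, c("phi", "psi", "omega")))
  }))
  stopifnot(nrow(tors) == 117)
  bb <- build_backbone_from_torsions(tors, sequence = seq117)
  # explicit guanidinium CZ of Arg65, extended along the CA -> CB direction
  ca <- bb$coords$CA[65, ]; cb <- bb$coords$CB[65, ]
  u <- unit(cb - ca)
  cz <- ca + 6.0 * u
  bb$extra <- data.frame(resno = 65L, atom = "CZ",
                         x = cz[1], y = cz[2], z = cz[3])
  # minimal DTZ ligand: imidazopyrazinone N1 4.2 A beyond CZ, plus ring stubs
  n1 <- cz + 4.2 * u
  v <- unit(pracma_cross(u, c(0, 0, 1)))
  het <- rbind(
    data.frame(group = "DTZ", atom = "N1", x = n1[1], y = n1[2], z = n1[3]),
    data.frame(group = "DTZ", atom = "C2", x = n1[1] + 1.4 * v[1],
               y = n1[2] + 1.4 * v[2], z = n1[3] + 1.4 * v[3]),
    data.frame(group = "DTZ", atom = "C3", x = n1[1] - 1.4 * v[1],
               y = n1[2] - 1.4 * v[2], z = n1[3] - 1.4 * v[3]),
    data.frame(group = "DTZ", atom = "O1", x = n1[1] + 2.6 * u[1],
               y = n1[2] + 2.6 * u[2], z = n1[3] + 2.6 * u[3]))
  bb$hetero <- het
  if (!is.null(path)) write_pdb(bb, path)
  bb
}
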