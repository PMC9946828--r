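#' Classify alignment columns into conserved and variable regions
#'
#' Structurally conserved regions (SCRs) are the alignment columns shared
#' across family members; variable regions are the loop columns that differ.
#' Columns whose gap fraction is at most `gap_threshold` are conserved;
#' conserved runs shorter than `min_segment_length` are demoted to variable.
#' Each variable segment gets loop length bounds
#' `(observed min - 1, observed max + 1)` clamped at 0, defining how far
#' insertion/deletion moves may resize that loop during hallucination.
#'
#' @param alignment named character vector of equal-length aligned sequences
#'   (gap character `-`).
#' @param gap_threshold maximum gap fraction for a conserved column.
#' @param min_segment_length minimum conserved run length (columns).
#' @return an object of class `region_annotation`: column classes, ordered
#'   segments, per-variable-segment loop length bounds, and per-member
#'   column-to-residue maps.
#' @export
classify_regions <- function(alignment, gap_threshold = 0.3,
                             min_segment_length = 3) {
  if (length(alignment) < 2) stop("alignment needs >= 2 sequences", call. = FALSE)
  w <- unique(nchar(alignment))
  if (length(w) != 1) stop("ragged alignment: unequal aligned lengths", call. = FALSE)
  if (w == 0) stop("empty alignment", call. = FALSE)
  mat <- do.call(rbind, strsplit(alignment, ""))
  gapfrac <- colMeans(mat == "-")
  conserved <- gapfrac <= gap_threshold
  # demote short conserved runs
  r <- rle(conserved)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] < min_segment_length) {
      conserved[starts[k]:ends[k]] <- FALSE
    }
  }
  build_annotation(mat, conserved)
}

# shared constructor: column classes + alignment matrix -> annotation
build_annotation <- function(mat, conserved) {
  w <- ncol(mat)
  r <- rle(conserved)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  segments <- data.frame(
    type = ifelse(r$values, "conserved", "variable"),
    start = starts, end = ends, stringsAsFactors = FALSE)
  member_maps <- lapply(seq_len(nrow(mat)), function(m) {
    nong <- mat[m, ] != "-"
    mm <- rep(NA_integer_, w)
    mm[nong] <- seq_len(sum(nong))
    mm
  })
  vseg <- which(segments$type == "variable")
  loop_bounds <- matrix(0L, length(vseg), 2,
                        dimnames = list(NULL, c("min", "max")))
  for (k in seq_along(vseg)) {
    cols <- segments$start[vseg[k]]:segments$end[vseg[k]]
    lens <- vapply(member_maps, function(mm) sum(!is.na(mm[cols])), integer(1))
    loop_bounds[k, ] <- c(max(0L, min(lens) - 1L), max(lens) + 1L)
  }
  structure(list(alignment_length = w,
                 column_class = ifelse(conserved, "conserved", "variable"),
                 conserved_cols = which(conserved),
                 segments = segments,
                 loop_bounds = loop_bounds,
                 member_maps = member_maps,
                 n_members = nrow(mat)),
            class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  cat(sprintf("<region_annotation> %d columns: %d conserved in %d segment(s), %d variable loop(s)\n",
              x$alignment_length, length(x$conserved_cols),
              sum(x$segments$type == "conserved"), nrow(x$loop_bounds)))
  invisible(x)
}

# observed loop lengths of one member, in variable-segment order
loop_lengths_of_member <- function(ann, member) {
  vseg <- which(ann$segments$type == "variable")
  vapply(vseg, function(s) {
    cols <- ann$segments$start[s]:ann$segments$end[s]
    sum(!is.na(ann$member_maps[[member]][cols]))
  }, integer(1))
}

#' Build family-wide restraint distributions
#'
#' Pools the observed binned 6D geometries of every family member over each
#' unordered pair of conserved alignment columns (members contribute where
#' both columns are non-gap), adds `pseudocount` smoothing mass to every bin
#' and normalizes. Pairs with zero support carry the uniform distribution.
#' Pairs are restrained regardless of contact status: the no-contact bin
#' carries the information that two columns sit apart.
#'
#' @param structures list of `backbone` objects, one per alignment member and
#'   in the same order.
#' @param alignment named character vector of aligned sequences.
#' @param annotation a `region_annotation` for the alignment.
#' @param spec a `bin_spec`.
#' @param pseudocount smoothing mass added to every bin before normalization;
#'   `NULL` (default) uses 1/(number of bins) per channel, which keeps every
#'   KL term finite while barely moving well-supported histograms.
#' @return an object of class `family_profile`.
#' @export
build_profile <- function(structures, alignment, annotation, spec = bin_spec(),
                          pseudocount = NULL) {
  if (length(structures) != length(alignment)) {
    stop("structures and alignment members differ in number", call. = FALSE)
  }
  if (annotation$alignment_length != unique(nchar(alignment)) ||
      annotation$n_members != length(alignment)) {
    stop("annotation does not match the alignment", call. = FALSE)
  }
  nm <- length(structures)
  for (m in seq_len(nm)) {
    nres <- sum(strsplit(alignment[[m]], "")[[1]] != "-")
    if (length(structures[[m]]$resid) != nres) {
      stop(sprintf("member %d: %d residues but %d non-gap columns", m,
                   length(structures[[m]]$resid), nres), call. = FALSE)
    }
  }
  cc <- annotation$conserved_cols
  C <- length(cc)
  if (C < 2) stop("need at least 2 conserved columns", call. = FALSE)
  pairs <- t(utils::combn(cc, 2))
  np <- nrow(pairs)
  channels <- c("d", "omega", "theta_fwd", "theta_rev", "phi_fwd", "phi_rev")
  base_ch <- c(d = "d", omega = "omega", theta_fwd = "theta", theta_rev = "theta",
               phi_fwd = "phi", phi_rev = "phi")
  counts <- lapply(base_ch, function(b) matrix(0, np, n_bins(spec, b)))
  names(counts) <- channels
  support <- integer(np)

  gmaps <- lapply(structures, function(s) compute_geometry(reconstruct_cb(s), spec))
  for (m in seq_len(nm)) {
    mm <- annotation$member_maps[[m]]
    gm <- gmaps[[m]]
    for (p in seq_len(np)) {
      i <- mm[pairs[p, 1]]; j <- mm[pairs[p, 2]]
      if (is.na(i) || is.na(j)) next
      bf <- observed_bins(gm, i, j, spec)   # a -> b direction
      br <- observed_bins(gm, j, i, spec)   # b -> a direction
      counts$d[p, bf[["d"]]] <- counts$d[p, bf[["d"]]] + 1
      counts$omega[p, bf[["omega"]]] <- counts$omega[p, bf[["omega"]]] + 1
      counts$theta_fwd[p, bf[["theta"]]] <- counts$theta_fwd[p, bf[["theta"]]] + 1
      counts$theta_rev[p, br[["theta"]]] <- counts$theta_rev[p, br[["theta"]]] + 1
      counts$phi_fwd[p, bf[["phi"]]] <- counts$phi_fwd[p, bf[["phi"]]] + 1
      counts$phi_rev[p, br[["phi"]]] <- counts$phi_rev[p, br[["phi"]]] + 1
      support[p] <- support[p] + 1L
    }
  }
  restraints <- counts
  for (ch in channels) {
    K <- ncol(counts[[ch]])
    eps <- if (is.null(pseudocount)) 1 / K else pseudocount
    sm <- counts[[ch]] + eps
    zero <- rowSums(sm) == 0            # only possible with eps = 0, support 0
    sm[zero, ] <- 1 / K
    restraints[[ch]] <- sm / rowSums(sm)
  }
  structure(list(annotation = annotation, spec = spec, pairs = pairs,
                 restraints = restraints, support = support,
                 pseudocount = pseudocount, n_members = nm),
            class = "family_profile")
}

#' @export
print.family_profile <- function(x, ...) {
  cat(sprintf("<family_profile> %d members, %d conserved-column pairs (support %d-%d)\n",
              x$n_members, nrow(x$pairs), min(x$support), max(x$support)))
  invisible(x)
}

PROFILE_FORMAT_VERSION <- 1L

#' Persist / restore a family profile
#'
#' The on-disk format is a JSON container: a header with the format version
#' and the explicit bin edges, then the annotation and the per-pair
#' distribution records. Distributions round-trip to better than 1e-12.
#'
#' @param profile a `family_profile`.
#' @param path file path.
#' @return `save_profile`: `path`, invisibly; `load_profile`: the restored
#'   `family_profile`.
#' @export
save_profile <- function(profile, path) {
  stopifnot(inherits(profile, "family_profile"))
  ann <- profile$annotation
  obj <- list(
    format = "famhal_profile",
    format_version = PROFILE_FORMAT_VERSION,
    bin_spec = bin_spec_to_list(profile$spec),
    annotation = list(alignment_length = ann$alignment_length,
                      column_class = ann$column_class,
                      segments = ann$segments,
                      loop_bounds = ann$loop_bounds,
                      member_maps = ann$member_maps,
                      n_members = ann$n_members),
    pairs = profile$pairs,
    support = profile$support,
    pseudocount = profile$pseudocount,
    n_members = profile$n_members,
    restraints = profile$restraints
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname save_profile
#' @export
load_profile <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop(sprintf("corrupt profile file: %s",
                                                   conditionMessage(e)), call. = FALSE))
  if (!identical(obj$format, "famhal_profile")) {
    stop("corrupt profile file: missing famhal_profile header", call. = FALSE)
  }
  if (!identical(as.integer(obj$format_version), PROFILE_FORMAT_VERSION)) {
    stop(sprintf("profile format version %s not supported (expected %d)",
                 obj$format_version, PROFILE_FORMAT_VERSION), call. = FALSE)
  }
  spec <- bin_spec_from_list(obj$bin_spec)
  a <- obj$annotation
  ann <- structure(list(
    alignment_length = as.integer(a$alignment_length),
    column_class = as.character(a$column_class),
    conserved_cols = which(a$column_class == "conserved"),
    segments = as.data.frame(a$segments),
    loop_bounds = matrix(as.integer(a$loop_bounds), ncol = 2,
                         dimnames = list(NULL, c("min", "max"))),
    member_maps = if (is.matrix(a$member_maps)) {
      lapply(seq_len(nrow(a$member_maps)),
             function(i) as.integer(a$member_maps[i, ]))
    } else {
      lapply(a$member_maps, as.integer)
    },
    n_members = as.integer(a$n_members)), class = "region_annotation")
  restraints <- lapply(obj$restraints, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  base_ch <- c(d = "d", omega = "omega", theta_fwd = "theta", theta_rev = "theta",
               phi_fwd = "phi", phi_rev = "phi")
  for (ch in names(base_ch)) {
    if (is.null(restraints[[ch]]) ||
        ncol(restraints[[ch]]) != n_bins(spec, base_ch[[ch]])) {
      stop(sprintf("corrupt profile file: channel %s has wrong bin count", ch),
           call. = FALSE)
    }
  }
  structure(list(annotation = ann, spec = spec,
                 pairs = matrix(as.integer(as.matrix(obj$pairs)), ncol = 2),
                 restraints = restraints,
                 support = as.integer(obj$support),
                 pseudocount = obj$pseudocount,
                 n_members = as.integer(obj$n_members)),
            class = "family_profile")
}

#' Read / write an aligned FASTA file
#'
#' Thin wrappers over bio3d's FASTA I/O exposing alignments as named
#' character vectors (gaps as `-`), the representation the classification and
#' profile builders consume.
#' @param path file path.
#' @return `read_alignment`: named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  fa <- bio3d::read.fasta(path)
  seqs <- apply(fa$ali, 1, paste, collapse = "")
  names(seqs) <- fa$id
  seqs
}

#' @rdname read_alignment
#' @param alignment named character vector of aligned sequences.
#' @export
write_alignment <- function(alignment, path) {
  bio3d::write.fasta(seqs = do.call(rbind, strsplit(alignment, "")),
                     ids = names(alignment), file = path)
  invisible(path)
}
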