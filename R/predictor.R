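DEFAULT_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Predicted inter-residue geometry distributions
#'
#' The output contract of any structure-prediction oracle: for every ordered
#' residue pair (i, j), i != j, and every channel, a normalized categorical
#' distribution over the [bin_spec()] bins. Entry `[i, j, ]` of the `theta`
#' and `phi` arrays is the i->j (forward) distribution; the j->i value lives
#' at `[j, i, ]`. `d` and `omega` are symmetric under pair swap.
#'
#' @param length number of residues.
#' @param d,omega,theta,phi arrays of dimension `length x length x n_bins`.
#' @param spec the `bin_spec` the distributions are defined on.
#' @param validate check normalization and symmetry (costs a pass over the
#'   arrays; constructors that guarantee validity may skip it).
#' @return an object of class `predicted_geometry`.
#' @export
predicted_geometry <- function(length, d, omega, theta, phi, spec,
                               validate = FALSE) {
  obj <- structure(list(length = length, d = d, omega = omega, theta = theta,
                        phi = phi, spec = spec),
                   class = "predicted_geometry")
  if (validate) validate_prediction(obj)
  obj
}

#' @export
print.predicted_geometry <- function(x, ...) {
  cat(sprintf("<predicted_geometry> %d residues, bins d:%d omega:%d theta:%d phi:%d\n",
              x$length, dim(x$d)[3], dim(x$omega)[3], dim(x$theta)[3], dim(x$phi)[3]))
  invisible(x)
}

#' Validate a predicted geometry against the contract
#'
#' Checks non-negativity, per-pair normalization (within 1e-9 over off-diagonal
#' pairs) and symmetry of the d and omega channels.
#' @param pred a `predicted_geometry`.
#' @param tol normalization tolerance.
#' @return `pred`, invisibly; errors on violation.
#' @export
validate_prediction <- function(pred, tol = 1e-9) {
  n <- pred$length
  off <- !diag(TRUE, n)
  for (ch in c("d", "omega", "theta", "phi")) {
    a <- pred[[ch]]
    if (any(a < -tol)) stop(sprintf("negative mass in channel %s", ch), call. = FALSE)
    s <- apply(a, c(1, 2), sum)
    if (any(abs(s[off] - 1) > 1e-6)) {
      stop(sprintf("channel %s distributions do not sum to 1", ch), call. = FALSE)
    }
  }
  for (ch in c("d", "omega")) {
    a <- pred[[ch]]
    at <- aperm(a, c(2, 1, 3))
    if (max(abs(a - at)) > 1e-6) {
      stop(sprintf("channel %s is not symmetric under pair swap", ch), call. = FALSE)
    }
  }
  invisible(pred)
}

#' Symmetrize the d and omega channels of a prediction
#'
#' External predictors with asymmetric distance/omega outputs are reconciled
#' by averaging the (i, j) and (j, i) distributions.
#' @param pred a `predicted_geometry`.
#' @return the symmetrized `predicted_geometry`.
#' @export
symmetrize_prediction <- function(pred) {
  for (ch in c("d", "omega")) {
    pred[[ch]] <- (pred[[ch]] + aperm(pred[[ch]], c(2, 1, 3))) / 2
  }
  pred
}

# ---- predictor registry ----------------------------------------------------

.predictor_registry <- new.env(parent = emptyenv())

#' Register / fetch structure predictors by name
#'
#' Predictors are deterministic functions from a sequence to a
#' [predicted_geometry()]; registering them by name lets config files select
#' the oracle.
#' @param name registry key.
#' @param predictor a `famhal_predictor`.
#' @return `register_predictor`: the predictor, invisibly; `get_predictor`:
#'   the registered predictor; `list_predictors`: character vector of names.
#' @export
register_predictor <- function(name, predictor) {
  stopifnot(inherits(predictor, "famhal_predictor"))
  assign(name, predictor, envir = .predictor_registry)
  invisible(predictor)
}

#' @rdname register_predictor
#' @export
get_predictor <- function(name) {
  if (!exists(name, envir = .predictor_registry)) {
    stop(sprintf("no predictor registered under '%s'", name), call. = FALSE)
  }
  get(name, envir = .predictor_registry)
}

#' @rdname register_predictor
#' @export
list_predictors <- function() ls(envir = .predictor_registry)

#' Run a predictor on a sequence
#'
#' Validates the sequence against the predictor's alphabet and minimum length,
#' then dispatches to the implementation. The optional `loop_lengths` vector
#' tells length-aware predictors (the surrogate) how the query's variable
#' loops are sized; when omitted the predictor infers a deterministic mapping
#' from the query length.
#'
#' @param predictor a `famhal_predictor`.
#' @param sequence amino-acid string.
#' @param loop_lengths optional integer vector of current loop lengths.
#' @return a `predicted_geometry`.
#' @export
predict_geometry <- function(predictor, sequence, loop_lengths = NULL) {
  stopifnot(inherits(predictor, "famhal_predictor"))
  aa <- strsplit(sequence, "")[[1]]
  if (length(aa) < 2) stop("sequence must have length >= 2", call. = FALSE)
  bad <- setdiff(aa, predictor$alphabet)
  if (length(bad)) {
    stop(sprintf("sequence letter(s) outside predictor alphabet: %s",
                 paste(unique(bad), collapse = ",")), call. = FALSE)
  }
  predictor$fn(aa, loop_lengths)
}

#' @export
print.famhal_predictor <- function(x, ...) {
  cat(sprintf("<famhal_predictor> %s (alphabet %d letters)\n", x$name,
              length(x$alphabet)))
  invisible(x)
}

# ---- surrogate -------------------------------------------------------------

# deterministic query-position -> template-position mapping.
# conserved segments map 1:1; a query loop of length ql maps into a template
# loop of length tl proportionally when ql <= tl, otherwise the first tl
# residues map 1:1 and the excess is unmapped (background-only pairs).
map_query_to_template <- function(annotation, query_loop_lengths,
                                  template_loop_lengths, template_map) {
  segs <- annotation$segments
  tmap <- integer(0)
  li <- 0L
  for (s in seq_along(segs$type)) {
    if (segs$type[s] == "conserved") {
      cols <- segs$start[s]:segs$end[s]
      tmap <- c(tmap, template_map[cols])
    } else {
      li <- li + 1L
      ql <- query_loop_lengths[li]
      tl <- template_loop_lengths[li]
      tpos <- if (tl > 0) {
        cols <- segs$start[s]:segs$end[s]
        stats::na.omit(template_map[cols])
      } else integer(0)
      if (ql == 0) next
      m <- if (tl == 0) {
        rep(NA_integer_, ql)
      } else if (ql <= tl) {
        tpos[ceiling(seq_len(ql) * tl / ql)]
      } else {
        c(tpos, rep(NA_integer_, ql - tl))
      }
      tmap <- c(tmap, m)
    }
  }
  tmap
}

# deterministic loop-length inference when the caller supplies none:
# start from the template's loop lengths and absorb the length difference one
# residue at a time, cycling left to right, clamped at zero.
infer_loop_lengths <- function(query_len, conserved_len, template_loop_lengths) {
  if (query_len < conserved_len) {
    stop("query shorter than the conserved region", call. = FALSE)
  }
  ll <- template_loop_lengths
  diff <- query_len - (conserved_len + sum(ll))
  k <- 0L
  while (diff != 0 && length(ll) > 0) {
    i <- (k %% length(ll)) + 1L
    if (diff > 0) { ll[i] <- ll[i] + 1L; diff <- diff - 1L }
    else if (ll[i] > 0) { ll[i] <- ll[i] - 1L; diff <- diff + 1L }
    k <- k + 1L
    if (k > 10000L) stop("cannot reconcile query length with loop bounds", call. = FALSE)
  }
  if (diff != 0) stop("query shorter than the conserved region", call. = FALSE)
  ll
}

#' Build the deterministic surrogate predictor
#'
#' A desk-scale stand-in for a trained structure-prediction network, so the
#' hallucination loop is exercisable end to end. For a query sequence the
#' surrogate outputs, for every residue pair, the mixture
#' `s * onehot(template geometry) + (1 - s) * uniform`, where
#' `s = logistic(kappa * m)` and `m` is the mean per-position compatibility of
#' the query with `compat_weights` over positions that map to scored template
#' positions. Sequences resembling the planted optimum therefore yield sharp,
#' template-consistent distograms; unrelated sequences yield near-uniform
#' ones — qualitatively the confidence behaviour of a real network.
#'
#' @param profile a `family_profile` (provides the region annotation and the
#'   reference member's column map).
#' @param template a `geometry_map` of the reference family member.
#' @param compat_weights matrix `template_length x alphabet` of per-position
#'   amino-acid scores; rows of `NA` mark unscored (loop) positions.
#' @param kappa sharpness of the logistic compatibility-to-confidence map
#'   (> 0; `kappa -> 0` gives the fixed half-mixture for every sequence).
#' @param alphabet predictor alphabet (columns of `compat_weights`).
#' @param ref_member index of the family member the template belongs to.
#' @return a `famhal_predictor` named `"surrogate"`.
#' @export
make_surrogate <- function(profile, template, compat_weights, kappa = 3,
                           alphabet = DEFAULT_ALPHABET, ref_member = 1L) {
  stopifnot(inherits(profile, "family_profile"), inherits(template, "geometry_map"))
  ann <- profile$annotation
  spec <- profile$spec
  template_map <- ann$member_maps[[ref_member]]
  if (max(template_map, na.rm = TRUE) != template$length) {
    stop("template length does not match the reference member", call. = FALSE)
  }
  if (!is.matrix(compat_weights) || nrow(compat_weights) != template$length ||
      ncol(compat_weights) != length(alphabet)) {
    stop("compat_weights must be template_length x alphabet", call. = FALSE)
  }
  colnames(compat_weights) <- alphabet
  if (kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  template_loops <- loop_lengths_of_member(ann, ref_member)
  conserved_len <- length(ann$conserved_cols)

  # precompute the template's observed bin index per ordered pair and channel
  nt <- template$length
  tb <- list(d = matrix(NA_integer_, nt, nt), omega = matrix(NA_integer_, nt, nt),
             theta = matrix(NA_integer_, nt, nt), phi = matrix(NA_integer_, nt, nt))
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (i == j) next
      b <- observed_bins(template, i, j, spec)
      for (ch in names(tb)) tb[[ch]][i, j] <- b[[ch]]
    }
  }
  scored <- !is.na(compat_weights[, 1])

  fn <- function(aa, loop_lengths) {
    L <- length(aa)
    if (is.null(loop_lengths)) {
      loop_lengths <- infer_loop_lengths(L, conserved_len, template_loops)
    }
    if (conserved_len + sum(loop_lengths) != L) {
      stop("loop_lengths inconsistent with query length", call. = FALSE)
    }
    tmap <- map_query_to_template(ann, loop_lengths, template_loops, template_map)
    mapped <- !is.na(tmap)
    use <- mapped
    use[mapped] <- scored[tmap[mapped]]
    m <- if (any(use)) {
      mean(compat_weights[cbind(tmap[use], match(aa[use], alphabet))])
    } else 0
    s <- stats::plogis(kappa * m)
    out <- list()
    for (ch in c("d", "omega", "theta", "phi")) {
      K <- n_bins(spec, ch)
      arr <- array((1 - s) / K, c(L, L, K))
      # add the sharp template component where both positions are mapped
      ij <- which(outer(mapped, mapped) & !diag(TRUE, L), arr.ind = TRUE)
      if (nrow(ij)) {
        bins <- tb[[ch]][cbind(tmap[ij[, 1]], tmap[ij[, 2]])]
        idx <- cbind(ij, bins)
        arr[idx] <- arr[idx] + s
      }
      # unmapped pairs stay diffuse: fold the sharp mass into uniform
      un <- which(!(outer(mapped, mapped)) & !diag(TRUE, L), arr.ind = TRUE)
      if (nrow(un)) {
        for (k in seq_len(K)) arr[cbind(un, k)] <- 1 / K
      }
      out[[ch]] <- arr
    }
    p <- predicted_geometry(L, out$d, out$omega, out$theta, out$phi, spec)
    attr(p, "s") <- s
    p
  }
  structure(list(name = "surrogate", fn = fn, alphabet = alphabet,
                 spec = spec, kappa = kappa, template_length = nt,
                 conserved_len = conserved_len, template_loops = template_loops),
            class = "famhal_predictor")
}

# ---- background ------------------------------------------------------------

#' Compute the background geometry distribution of a predictor
#'
#' The background is defined operationally as the mean prediction over
#' uniformly random sequences: per channel, predictor outputs are pooled over
#' all ordered pairs of each random sequence (optionally stratified by
#' sequence-separation band), averaged over sequences, floored at `floor` and
#' renormalized. It is the reference against which prediction sharpness
#' (confidence) is measured.
#'
#' @param predictor a `famhal_predictor`.
#' @param lengths integer vector of sequence lengths to draw from.
#' @param n_sequences number of random sequences to average (default 100).
#' @param seed RNG seed (background is reproducible given the seed).
#' @param bands optional list of separation bands, each `c(lo, hi)` on
#'   `|i - j|`; `NULL` (default) pools all separations together.
#' @param floor strict-positivity floor applied before renormalization,
#'   guaranteeing finite KL terms.
#' @return an object of class `background_geometry`: per channel either a
#'   probability vector or (stratified) a `bands x bins` matrix.
#' @export
compute_background <- function(predictor, lengths, n_sequences = 100, seed = 1,
                               bands = NULL, floor = 1e-8) {
  stopifnot(n_sequences >= 1)
  spec <- predictor$spec
  nb <- if (is.null(bands)) 1L else length(bands)
  acc <- lapply(c(d = "d", omega = "omega", theta = "theta", phi = "phi"),
                function(ch) matrix(0, nb, n_bins(spec, ch)))
  with_rng_seed(seed, {
    for (r in seq_len(n_sequences)) {
      L <- if (length(lengths) == 1) lengths else sample(lengths, 1)
      aa <- sample(predictor$alphabet, L, replace = TRUE)
      pred <- predictor$fn(aa, NULL)
      sep <- abs(outer(seq_len(L), seq_len(L), "-"))
      off <- sep > 0
      for (ch in names(acc)) {
        a <- pred[[ch]]
        K <- dim(a)[3]
        for (b in seq_len(nb)) {
          m <- if (is.null(bands)) off else
            off & sep >= bands[[b]][1] & sep <= bands[[b]][2]
          if (!any(m)) next
          pooled <- vapply(seq_len(K), function(k) mean(a[, , k][m]), numeric(1))
          acc[[ch]][b, ] <- acc[[ch]][b, ] + pooled / n_sequences
        }
      }
    }
  })
  for (ch in names(acc)) {
    acc[[ch]] <- pmax(acc[[ch]], floor)
    acc[[ch]] <- acc[[ch]] / rowSums(acc[[ch]])
    if (is.null(bands)) acc[[ch]] <- acc[[ch]][1, ]
  }
  structure(list(d = acc$d, omega = acc$omega, theta = acc$theta, phi = acc$phi,
                 bands = bands, spec = spec),
            class = "background_geometry")
}

#' @export
print.background_geometry <- function(x, ...) {
  cat(sprintf("<background_geometry> %s\n",
              if (is.null(x$bands)) "pooled over all separations"
              else sprintf("%d separation bands", length(x$bands))))
  invisible(x)
}

#' Background distribution for one channel (and separation)
#' @param bg a `background_geometry`.
#' @param channel one of d/omega/theta/phi.
#' @param sep sequence separation `|i - j|` (used only when stratified).
#' @return probability vector over the channel's bins.
#' @export
background_dist <- function(bg, channel, sep = NULL) {
  v <- bg[[channel]]
  if (is.null(bg$bands)) return(v)
  if (is.null(sep)) stop("stratified background needs a separation", call. = FALSE)
  for (b in seq_along(bg$bands)) {
    if (sep >= bg$bands[[b]][1] && sep <= bg$bands[[b]][2]) return(v[b, ])
  }
  v[nrow(v), ]
}

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
with_rng_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}
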