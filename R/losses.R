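#' Loss configuration
#'
#' Weights for the multicomponent hallucination loss. The total is
#' `w_restraint * restraint + w_confidence * confidence`, where the restraint
#' term scores conserved-pair predictions against the family profile and the
#' confidence term is the negative mean KL divergence of variable-pair
#' predictions from background. Channel weights multiply the four geometry
#' channels inside both terms (the directional theta/phi channels share one
#' weight per direction pair).
#'
#' @param w_restraint,w_confidence component weights (>= 0).
#' @param channel_weights named numeric vector with entries `d`, `omega`,
#'   `theta`, `phi`.
#' @param kl_floor positive floor applied to log arguments, keeping every
#'   loss finite for any normalized input.
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(w_restraint = 1, w_confidence = 1,
                        channel_weights = c(d = 1, omega = 1, theta = 1, phi = 1),
                        kl_floor = 1e-8) {
  stopifnot(is.finite(w_restraint), w_restraint >= 0,
            is.finite(w_confidence), w_confidence >= 0,
            kl_floor > 0, all(is.finite(channel_weights)),
            all(channel_weights >= 0))
  cw <- channel_weights[c("d", "omega", "theta", "phi")]
  if (anyNA(cw)) stop("channel_weights needs entries d, omega, theta, phi", call. = FALSE)
  structure(list(w_restraint = w_restraint, w_confidence = w_confidence,
                 channel_weights = cw, kl_floor = kl_floor),
            class = "loss_config")
}

# the six distribution slots per unordered pair, with their channel weights
SLOT_CHANNEL <- c(d = "d", omega = "omega", theta_fwd = "theta",
                  theta_rev = "theta", phi_fwd = "phi", phi_rev = "phi")

slot_weights <- function(cfg) unname(cfg$channel_weights[SLOT_CHANNEL])

#' Kullback-Leibler divergence between two categorical distributions
#'
#' `sum(p * log(p / q))` in nats, with `q` floored at `floor` and renormalized
#' so the result is finite for any normalized input; `p` entries of zero
#' contribute zero. Non-negative by Gibbs' inequality.
#'
#' @param p,q non-negative vectors of equal length summing to 1 (within 1e-6).
#' @param floor positive floor for `q`.
#' @return divergence in nats (>= 0 up to flooring).
#' @export
kl_divergence <- function(p, q, floor = 1e-8) {
  if (length(p) != length(q)) stop("p and q differ in length", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6 || any(p < 0) || any(q < 0)) {
    stop("p and q must be distributions (non-negative, summing to 1)", call. = FALSE)
  }
  qf <- pmax(q, floor)
  qf <- qf / sum(qf)
  pos <- p > 0
  sum(p[pos] * log(p[pos] / qf[pos]))
}

# cross-entropy -sum(r * log(pred)) with flooring on pred
cross_entropy <- function(r, pred, floor) {
  pos <- r > 0
  -sum(r[pos] * log(pmax(pred[pos], floor)))
}

# invert a column map: conserved alignment column -> sequence position
conserved_positions <- function(column_map, conserved_cols) {
  pos <- match(conserved_cols, column_map)
  if (anyNA(pos)) {
    stop(sprintf("conserved column(s) %s not mapped to any sequence position",
                 paste(conserved_cols[is.na(pos)], collapse = ",")), call. = FALSE)
  }
  pos
}

#' Restraint loss: consistency with the family profile
#'
#' Channel-weighted mean, over all conserved-column pairs, of the
#' cross-entropy of the predicted distributions against the family restraint
#' distributions: `-sum(restraint * log(pred))` per slot. Lower means more
#' consistent with the family geometry. Cross-entropy differs from
#' KL(restraint || pred) only by the (fixed) entropy of the restraints, so
#' the minimizer and all move deltas are identical.
#'
#' @param pred a `predicted_geometry` for the current sequence.
#' @param profile a `family_profile`.
#' @param column_map integer vector, sequence position -> alignment column
#'   (`NA` at variable-loop positions).
#' @param cfg a `loss_config`.
#' @return scalar loss in nats.
#' @export
restraint_loss <- function(pred, profile, column_map, cfg = loss_config()) {
  cc <- profile$annotation$conserved_cols
  pos <- conserved_positions(column_map, cc)
  pairs <- profile$pairs
  w <- slot_weights(cfg)
  if (sum(w) == 0) return(0)
  fl <- cfg$kl_floor
  ii <- pos[match(pairs[, 1], cc)]
  jj <- pos[match(pairs[, 2], cc)]
  n <- pred$length
  # rows of an (n, n, K) array at ordered index pairs, as an (npair, K) matrix
  slot_pred <- function(A, a, b) {
    K <- dim(A)[3]
    matrix(A[as.vector(outer(a + (b - 1) * n, (seq_len(K) - 1) * n * n, "+"))], length(a), K)
  }
  ce_slot <- function(R, P) -rowSums(R * log(pmax(P, fl)))
  ce <- cbind(
    ce_slot(profile$restraints$d, slot_pred(pred$d, ii, jj)),
    ce_slot(profile$restraints$omega, slot_pred(pred$omega, ii, jj)),
    ce_slot(profile$restraints$theta_fwd, slot_pred(pred$theta, ii, jj)),
    ce_slot(profile$restraints$theta_rev, slot_pred(pred$theta, jj, ii)),
    ce_slot(profile$restraints$phi_fwd, slot_pred(pred$phi, ii, jj)),
    ce_slot(profile$restraints$phi_rev, slot_pred(pred$phi, jj, ii)))
  mean(as.vector(ce %*% w) / sum(w))
}

#' Enumerate variable pairs of a sequence
#'
#' All unordered position pairs with at least one variable-region (loop)
#' residue — the domain of the confidence loss.
#' @param column_map integer vector, sequence position -> alignment column,
#'   `NA` at variable positions.
#' @return 2-column matrix of position pairs (i < j); zero rows when the
#'   sequence has no variable positions.
#' @export
variable_pairs <- function(column_map) {
  n <- length(column_map)
  isvar <- is.na(column_map)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- isvar[idx[, 1]] | isvar[idx[, 2]]
  idx[keep, , drop = FALSE]
}

#' Confidence loss: negative divergence from background
#'
#' The negative channel-weighted mean, over variable pairs, of
#' `KL(prediction || background)`. Minimizing the total loss therefore drives
#' variable-pair predictions away from the uninformative background, i.e.
#' towards confident (sharp) geometry — the free-hallucination signal.
#'
#' @param pred a `predicted_geometry`.
#' @param background a `background_geometry`.
#' @param pairs 2-column matrix of variable position pairs (see
#'   [variable_pairs()]).
#' @param cfg a `loss_config`.
#' @return scalar loss (<= 0); 0 with a message when `pairs` is empty.
#' @export
confidence_loss <- function(pred, background, pairs, cfg = loss_config()) {
  if (is.null(pairs) || nrow(pairs) == 0) {
    message("confidence_loss: no variable pairs; term is 0")
    return(0)
  }
  w <- slot_weights(cfg)
  if (sum(w) == 0) return(0)
  fl <- cfg$kl_floor
  n <- pred$length
  ii <- pairs[, 1]; jj <- pairs[, 2]
  sep <- abs(ii - jj)
  slot_pred <- function(A, a, b) {
    K <- dim(A)[3]
    matrix(A[as.vector(outer(a + (b - 1) * n, (seq_len(K) - 1) * n * n, "+"))], length(a), K)
  }
  kl_slot <- function(P, channel) {
    # floored, renormalized background per pair row
    Q <- t(vapply(sep, function(s) {
      q <- pmax(background_dist(background, channel, s), fl)
      q / sum(q)
    }, numeric(dim(P)[2])))
    terms <- P * (log(P) - log(Q))
    terms[P == 0] <- 0
    rowSums(terms)
  }
  kl <- cbind(
    kl_slot(slot_pred(pred$d, ii, jj), "d"),
    kl_slot(slot_pred(pred$omega, ii, jj), "omega"),
    kl_slot(slot_pred(pred$theta, ii, jj), "theta"),
    kl_slot(slot_pred(pred$theta, jj, ii), "theta"),
    kl_slot(slot_pred(pred$phi, ii, jj), "phi"),
    kl_slot(slot_pred(pred$phi, jj, ii), "phi"))
  -mean(as.vector(kl %*% w) / sum(w))
}

#' Total multicomponent loss
#'
#' Combines the restraint and confidence terms with the configured weights
#' into a `loss_report`.
#'
#' @param pred a `predicted_geometry` for the current sequence.
#' @param profile a `family_profile`.
#' @param background a `background_geometry`.
#' @param column_map sequence position -> alignment column (`NA` at loops).
#' @param cfg a `loss_config`.
#' @return an object of class `loss_report` with fields `restraint`,
#'   `confidence`, `total`, `n_restraint_pairs`, `n_variable_pairs`.
#' @export
total_loss <- function(pred, profile, background, column_map,
                       cfg = loss_config()) {
  vp <- variable_pairs(column_map)
  r <- restraint_loss(pred, profile, column_map, cfg)
  conf <- if (nrow(vp) == 0) 0 else confidence_loss(pred, background, vp, cfg)
  structure(list(restraint = r, confidence = conf,
                 total = cfg$w_restraint * r + cfg$w_confidence * conf,
                 n_restraint_pairs = nrow(profile$pairs),
                 n_variable_pairs = nrow(vp)),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("<loss_report> total %.4f (restraint %.4f over %d pairs, confidence %.4f over %d pairs)\n",
              x$total, x$restraint, x$n_restraint_pairs, x$confidence,
              x$n_variable_pairs))
  invisible(x)
}
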