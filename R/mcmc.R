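#' Construct a hallucination state
#'
#' A state holds the current sequence together with the bookkeeping that
#' survives insertions and deletions: the sequence-position -> alignment-column
#' map for conserved positions (`NA` with loop-local coordinates at variable
#' positions), the current loop lengths, and the frozen positions whose
#' identities may never change (the stand-in for preserving designed
#' hydrogen-bond networks).
#'
#' @param sequence amino-acid string, laid out segment by segment in alignment
#'   order (conserved segments at full length, each variable loop at its
#'   current length).
#' @param annotation a `region_annotation`.
#' @param loop_lengths integer vector of current loop lengths, one per
#'   variable segment, each within its bounds.
#' @param frozen integer vector of sequence positions exempt from mutation;
#'   must be conserved-region positions.
#' @return an object of class `hallucination_state` with fields `sequence`,
#'   `column_map`, `loop_id`, `loop_pos`, `loop_lengths`, `frozen_cols`,
#'   `loss` (NULL until scored), `iteration`.
#' @export
hallucination_state <- function(sequence, annotation, loop_lengths,
                                frozen = integer(0)) {
  aa <- strsplit(sequence, "")[[1]]
  check_loop_bounds(annotation, loop_lengths)
  bk <- layout_positions(annotation, loop_lengths)
  if (length(aa) != length(bk$column_map)) {
    stop(sprintf("sequence length %d != conserved length + loop lengths (%d)",
                 length(aa), length(bk$column_map)), call. = FALSE)
  }
  frozen <- as.integer(frozen)
  if (length(frozen) && anyNA(bk$column_map[frozen])) {
    stop("frozen positions must be conserved-region positions", call. = FALSE)
  }
  structure(list(sequence = aa, column_map = bk$column_map, loop_id = bk$loop_id,
                 loop_pos = bk$loop_pos, loop_lengths = as.integer(loop_lengths),
                 frozen_cols = bk$column_map[frozen], annotation = annotation,
                 loss = NULL, iteration = 0L),
            class = "hallucination_state")
}

# sequence layout for given loop lengths: per-position alignment column (NA in
# loops), loop id and loop-local coordinate
layout_positions <- function(annotation, loop_lengths) {
  segs <- annotation$segments
  vseg <- which(segs$type == "variable")
  if (length(loop_lengths) != length(vseg)) {
    stop(sprintf("expected %d loop lengths, got %d", length(vseg),
                 length(loop_lengths)), call. = FALSE)
  }
  column_map <- integer(0); loop_id <- integer(0); loop_pos <- integer(0)
  li <- 0L
  for (s in seq_along(segs$type)) {
    if (segs$type[s] == "conserved") {
      cols <- segs$start[s]:segs$end[s]
      column_map <- c(column_map, cols)
      loop_id <- c(loop_id, rep(NA_integer_, length(cols)))
      loop_pos <- c(loop_pos, rep(NA_integer_, length(cols)))
    } else {
      li <- li + 1L
      ll <- loop_lengths[li]
      if (ll > 0) {
        column_map <- c(column_map, rep(NA_integer_, ll))
        loop_id <- c(loop_id, rep(li, ll))
        loop_pos <- c(loop_pos, seq_len(ll))
      }
    }
  }
  list(column_map = column_map, loop_id = loop_id, loop_pos = loop_pos)
}

check_loop_bounds <- function(annotation, loop_lengths) {
  b <- annotation$loop_bounds
  bad <- which(loop_lengths < b[, "min"] | loop_lengths > b[, "max"])
  if (length(bad)) {
    stop(sprintf("loop %d length %d outside bounds [%d, %d]", bad[1],
                 loop_lengths[bad[1]], b[bad[1], "min"], b[bad[1], "max"]),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.hallucination_state <- function(x, ...) {
  cat(sprintf("<hallucination_state> %s (%d aa, loops %s)%s\n",
              paste(x$sequence, collapse = ""), length(x$sequence),
              paste(x$loop_lengths, collapse = "/"),
              if (is.null(x$loss)) "" else sprintf(", total loss %.4f", x$loss$total)))
  invisible(x)
}

#' Frozen sequence positions of a state
#' @param state a `hallucination_state`.
#' @return integer vector of current sequence positions that are frozen.
#' @export
frozen_positions <- function(state) {
  which(state$column_map %in% state$frozen_cols)
}

#' Annealing schedule
#'
#' Temperature per step, from `T_initial` at the first step to `T_final` at
#' the last, interpolated geometrically (default) or linearly.
#'
#' @param T_initial,T_final temperatures (> 0, `T_final <= T_initial`).
#' @param n_steps number of MCMC steps.
#' @param mode `"geometric"` or `"linear"`.
#' @return numeric vector of length `n_steps` (class `anneal_schedule`).
#' @export
anneal_schedule <- function(T_initial = 0.1, T_final = 0.001, n_steps = 1000,
                            mode = c("geometric", "linear")) {
  mode <- match.arg(mode)
  stopifnot(T_initial > 0, T_final > 0, T_final <= T_initial, n_steps >= 0)
  if (n_steps == 0) return(structure(numeric(0), class = "anneal_schedule"))
  f <- if (n_steps == 1) 0 else (seq_len(n_steps) - 1) / (n_steps - 1)
  temps <- switch(mode,
                  geometric = T_initial * (T_final / T_initial)^f,
                  linear = T_initial + (T_final - T_initial) * f)
  structure(temps, class = "anneal_schedule",
            T_initial = T_initial, T_final = T_final, mode = mode)
}

#' Propose an MCMC move
#'
#' Draws a move kind from `move_probs` (renormalized over the kinds that are
#' currently legal), then a uniform legal realization: substitutions pick a
#' uniform non-frozen position and a uniform residue different from the
#' current one; insertions pick a uniform loop below its maximum length, a
#' uniform slot within it and a uniform residue; deletions pick a uniform
#' loop above its minimum and a uniform residue of it. Draws use R's global
#' RNG stream.
#'
#' @param state a `hallucination_state`.
#' @param move_probs numeric vector `c(substitute, insert, delete)` summing
#'   to 1.
#' @param alphabet residue alphabet for substitutions/insertions.
#' @return a `move_proposal`: list with `kind`, `position`, `residue`,
#'   `loop_id`.
#' @export
propose_move <- function(state, move_probs = c(0.85, 0.075, 0.075),
                         alphabet = DEFAULT_ALPHABET) {
  stopifnot(length(move_probs) == 3, abs(sum(move_probs) - 1) < 1e-9)
  b <- state$annotation$loop_bounds
  frozen <- frozen_positions(state)
  can_sub <- length(state$sequence) > length(frozen)
  can_ins <- any(state$loop_lengths < b[, "max"])
  can_del <- any(state$loop_lengths > b[, "min"] & state$loop_lengths > 0)
  legal <- c(can_sub, can_ins, can_del)
  p <- move_probs * legal
  if (sum(p) == 0) {
    stop("no legal move: all loops at bounds and all positions frozen", call. = FALSE)
  }
  kind <- c("substitute", "insert", "delete")[
    sample.int(3, 1, prob = p / sum(p))]
  if (kind == "substitute") {
    cand <- setdiff(seq_along(state$sequence), frozen)
    pos <- cand[sample.int(length(cand), 1)]
    res <- sample(setdiff(alphabet, state$sequence[pos]), 1)
    move <- list(kind = kind, position = pos, residue = res, loop_id = NA_integer_)
  } else if (kind == "insert") {
    loops <- which(state$loop_lengths < b[, "max"])
    li <- loops[sample.int(length(loops), 1)]
    slot <- sample.int(state$loop_lengths[li] + 1L, 1)  # 1..len+1
    res <- sample(alphabet, 1)
    move <- list(kind = kind, position = loop_slot_position(state, li, slot),
                 residue = res, loop_id = li, slot = slot)
  } else {
    loops <- which(state$loop_lengths > b[, "min"] & state$loop_lengths > 0)
    li <- loops[sample.int(length(loops), 1)]
    slot <- sample.int(state$loop_lengths[li], 1)
    pos <- which(!is.na(state$loop_id) & state$loop_id == li &
                   state$loop_pos == slot)
    move <- list(kind = kind, position = pos, residue = NA_character_,
                 loop_id = li, slot = slot)
  }
  structure(move, class = "move_proposal")
}

# sequence position where an inserted residue would land (slot k of loop li
# means the new residue becomes the loop's k-th residue)
loop_slot_position <- function(state, li, slot) {
  lp <- which(!is.na(state$loop_id) & state$loop_id == li)
  if (length(lp) == 0) {
    # empty loop: position right after the preceding segment
    segs <- state$annotation$segments
    vseg <- which(segs$type == "variable")[li]
    prev_cols <- if (vseg > 1) segs$end[vseg - 1] else 0
    if (prev_cols == 0) return(1L)
    return(which(state$column_map == prev_cols) + 1L)
  }
  lp[1] + slot - 1L
}

#' Apply a move to a state
#'
#' Returns a new state with the move applied and all bookkeeping (column map,
#' loop-local coordinates, loop lengths) recomputed; conserved positions keep
#' their alignment columns across indels, frozen identities are untouched, and
#' the input state is not modified. The loss of the new state is `NULL`
#' (stale) until rescored.
#'
#' @param state a `hallucination_state`.
#' @param move a `move_proposal`.
#' @return a new `hallucination_state`.
#' @export
apply_move <- function(state, move) {
  aa <- state$sequence
  ll <- state$loop_lengths
  if (move$kind == "substitute") {
    if (move$position %in% frozen_positions(state)) {
      stop("illegal move: substitution at a frozen position", call. = FALSE)
    }
    aa[move$position] <- move$residue
  } else if (move$kind == "insert") {
    b <- state$annotation$loop_bounds
    if (ll[move$loop_id] + 1L > b[move$loop_id, "max"]) {
      stop("illegal move: loop already at maximum length", call. = FALSE)
    }
    pos <- move$position
    aa <- append(aa, move$residue, after = pos - 1L)
    ll[move$loop_id] <- ll[move$loop_id] + 1L
  } else if (move$kind == "delete") {
    b <- state$annotation$loop_bounds
    if (ll[move$loop_id] - 1L < b[move$loop_id, "min"] || ll[move$loop_id] == 0) {
      stop("illegal move: loop already at minimum length", call. = FALSE)
    }
    if (is.na(state$loop_id[move$position]) ||
        state$loop_id[move$position] != move$loop_id) {
      stop("illegal move: deletion outside the named loop", call. = FALSE)
    }
    aa <- aa[-move$position]
    ll[move$loop_id] <- ll[move$loop_id] - 1L
  } else {
    stop(sprintf("unknown move kind '%s'", move$kind), call. = FALSE)
  }
  bk <- layout_positions(state$annotation, ll)
  new <- state
  new$sequence <- aa
  new$column_map <- bk$column_map
  new$loop_id <- bk$loop_id
  new$loop_pos <- bk$loop_pos
  new$loop_lengths <- ll
  new$loss <- NULL
  new
}

#' Metropolis acceptance
#'
#' Accepts with probability `min(1, exp(-delta_loss / temperature))`; moves
#' that do not increase the loss are always accepted. Draws one uniform
#' variate from the global RNG stream when the decision is stochastic.
#'
#' @param delta_loss finite loss change of the proposed move.
#' @param temperature temperature (> 0).
#' @return logical.
#' @export
metropolis_accept <- function(delta_loss, temperature) {
  stopifnot(is.finite(delta_loss), temperature > 0)
  if (delta_loss <= 0) return(TRUE)
  stats::runif(1) < exp(-delta_loss / temperature)
}

#' Run a simulated-annealing hallucination trajectory
#'
#' Executes `length(schedule)` propose -> apply -> predict -> score -> accept
#' cycles starting from `start_sequence`, recording every step, and returns
#' the best state by total loss (ties resolved to the earliest iteration).
#' Bit-reproducible given `seed`, the inputs and a deterministic predictor.
#'
#' @param start_sequence amino-acid string consistent with the profile's
#'   annotation at `start_loop_lengths`.
#' @param profile a `family_profile`.
#' @param background a `background_geometry`.
#' @param predictor a `famhal_predictor`.
#' @param schedule an [anneal_schedule()] (its length is the step count).
#' @param move_probs `c(substitute, insert, delete)` probabilities.
#' @param cfg a `loss_config`.
#' @param seed integer seed for the single RNG stream driving all draws.
#' @param start_loop_lengths loop lengths of the start sequence; default: the
#'   per-loop floor of the mean of the bounds.
#' @param frozen frozen sequence positions (conserved region only).
#' @param alphabet move alphabet; defaults to the predictor's.
#' @param cache cache predictions by sequence (helps when rejected sequences
#'   are re-proposed).
#' @return an object of class `hallucination_run`: list with `best`, `final`
#'   (both scored states), and `trajectory` (data frame with one row per step:
#'   iteration, kind, position, residue, delta, temperature, accepted,
#'   restraint, confidence, total).
#' @export
run_hallucination <- function(start_sequence, profile, background, predictor,
                              schedule = anneal_schedule(n_steps = 1000),
                              move_probs = c(0.85, 0.075, 0.075),
                              cfg = loss_config(), seed = 1,
                              start_loop_lengths = NULL,
                              frozen = integer(0),
                              alphabet = predictor$alphabet,
                              cache = TRUE) {
  ann <- profile$annotation
  if (is.null(start_loop_lengths)) {
    b <- ann$loop_bounds
    start_loop_lengths <- as.integer(floor((b[, "min"] + b[, "max"]) / 2))
  }
  state <- hallucination_state(start_sequence, ann, start_loop_lengths, frozen)
  memo <- if (cache) new.env(parent = emptyenv()) else NULL
  score <- function(st) {
    key <- paste(c(st$sequence, "|", st$loop_lengths), collapse = "")
    if (!is.null(memo) && !is.null(memo[[key]])) return(memo[[key]])
    pred <- predict_geometry(predictor, paste(st$sequence, collapse = ""),
                             loop_lengths = st$loop_lengths)
    rep <- total_loss(pred, profile, background, st$column_map, cfg)
    if (!is.null(memo)) memo[[key]] <- rep
    rep
  }
  n_steps <- length(schedule)
  with_rng_seed(seed, {
    state$loss <- score(state)
    best <- state
    traj <- vector("list", n_steps)
    for (it in seq_len(n_steps)) {
      temp <- schedule[it]
      move <- propose_move(state, move_probs, alphabet)
      cand <- apply_move(state, move)
      cand$loss <- score(cand)
      delta <- cand$loss$total - state$loss$total
      acc <- metropolis_accept(delta, temp)
      if (acc) {
        state <- cand
        state$iteration <- it
        if (state$loss$total < best$loss$total) best <- state
      }
      traj[[it]] <- data.frame(
        iteration = it, kind = move$kind, position = move$position,
        residue = if (is.na(move$residue)) "-" else move$residue,
        delta = delta, temperature = temp, accepted = acc,
        restraint = state$loss$restraint, confidence = state$loss$confidence,
        total = state$loss$total)
    }
  })
  trajectory <- if (n_steps) do.call(rbind, traj) else
    data.frame(iteration = integer(), kind = character(), position = integer(),
               residue = character(), delta = numeric(), temperature = numeric(),
               accepted = logical(), restraint = numeric(), confidence = numeric(),
               total = numeric())
  structure(list(best = best, final = state, trajectory = trajectory,
                 seed = seed, n_steps = n_steps),
            class = "hallucination_run")
}

#' @export
print.hallucination_run <- function(x, ...) {
  cat(sprintf("<hallucination_run> %d steps (seed %d): best total loss %.4f at iteration %d\n",
              x$n_steps, x$seed, x$best$loss$total, x$best$iteration))
  cat(sprintf("  best sequence: %s\n", paste(x$best$sequence, collapse = "")))
  invisible(x)
}

#' Write a trajectory log as tab-separated text
#' @param run a `hallucination_run`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(run, path) {
  utils::write.table(run$trajectory, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Best sequence of a run, as a FASTA-ready string
#' @param run a `hallucination_run`.
#' @return amino-acid string.
#' @export
best_sequence <- function(run) paste(run$best$sequence, collapse = "")
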