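test_that("hallucination_state enforces layout, bounds and frozen-position rules", {
  pp <- small_planted(n_random = 50)
  ann <- pp$profile$annotation
  st <- hallucination_state(pp$start_sequence, ann, pp$start_loop_lengths)
  # conserved columns strictly increasing in the column map
  cm <- st$column_map[!is.na(st$column_map)]
  expect_true(all(diff(cm) > 0))
  # sequence length = conserved length + sum of loops
  expect_equal(length(st$sequence),
               length(ann$conserved_cols) + sum(st$loop_lengths))
  expect_error(hallucination_state(pp$start_sequence, ann,
                                   pp$start_loop_lengths + 10), "outside bounds")
  # frozen must be conserved positions
  loop_pos <- which(is.na(st$column_map))[1]
  expect_error(hallucination_state(pp$start_sequence, ann,
                                   pp$start_loop_lengths, frozen = loop_pos),
               "conserved")
})

test_that("propose_move respects legality constraints and frequencies", {
  pp <- small_planted(n_random = 50)
  ann <- pp$profile$annotation
  st <- hallucination_state(pp$start_sequence, ann, pp$start_loop_lengths)

  # pure substitution
  set.seed(1)
  for (k in 1:50) {
    mv <- propose_move(st, c(1, 0, 0))
    expect_equal(mv$kind, "substitute")
    expect_false(mv$position %in% frozen_positions(st))
    expect_false(identical(st$sequence[mv$position], mv$residue))
  }

  # all loops at max length: insertions renormalized away
  st_max <- hallucination_state(
    paste(rep("A", length(ann$conserved_cols) + sum(ann$loop_bounds[, "max"])),
          collapse = ""),
    ann, ann$loop_bounds[, "max"])
  set.seed(2)
  kinds <- replicate(2000, propose_move(st_max, c(0.2, 0.6, 0.2))$kind)
  expect_false("insert" %in% kinds)

  # frozen positions never proposed for substitution
  froz <- which(!is.na(st$column_map))[1:3]
  st_frozen <- hallucination_state(pp$start_sequence, ann,
                                   pp$start_loop_lengths, frozen = froz)
  set.seed(3)
  pos <- replicate(500, propose_move(st_frozen, c(1, 0, 0))$position)
  expect_true(all(!pos %in% froz))

  # empirical kind frequencies match move_probs within 3 sigma (binomial)
  probs <- c(0.7, 0.15, 0.15)
  set.seed(4)
  kinds <- replicate(20000, propose_move(st, probs)$kind)
  for (k in 1:3) {
    nm <- c("substitute", "insert", "delete")[k]
    phat <- mean(kinds == nm)
    sigma <- sqrt(probs[k] * (1 - probs[k]) / 20000)
    expect_lt(abs(phat - probs[k]), 3 * sigma + 1e-12)
  }

  # no legal move at all
  ann0 <- pp$profile$annotation
  ann0$loop_bounds[, ] <- c(2L, 2L)
  st0 <- hallucination_state(pp$start_sequence, ann0, pp$start_loop_lengths,
                             frozen = which(!is.na(st$column_map)))
  expect_error(propose_move(st0, c(0, 0.5, 0.5)), "no legal move")
})

test_that("apply_move keeps bookkeeping consistent across moves", {
  pp <- small_planted(n_random = 50)
  ann <- pp$profile$annotation
  st <- hallucination_state(pp$start_sequence, ann, pp$start_loop_lengths)

  # substitute then substitute back restores the sequence
  pos <- which(!is.na(st$column_map))[2]
  old <- st$sequence[pos]
  st2 <- apply_move(st, structure(list(kind = "substitute", position = pos,
                                       residue = "W", loop_id = NA),
                                  class = "move_proposal"))
  expect_equal(st2$sequence[pos], "W")
  st3 <- apply_move(st2, structure(list(kind = "substitute", position = pos,
                                        residue = old, loop_id = NA),
                                   class = "move_proposal"))
  expect_equal(st3$sequence, st$sequence)
  expect_equal(st3$column_map, st$column_map)
  # the input state is untouched
  expect_equal(st$sequence[pos], old)

  # insert at loop slot k then delete at k round-trips
  li <- 1L
  slot <- 1L
  ins_pos <- famhal:::loop_slot_position(st, li, slot)
  st4 <- apply_move(st, structure(list(kind = "insert", position = ins_pos,
                                       residue = "G", loop_id = li, slot = slot),
                                  class = "move_proposal"))
  expect_equal(length(st4$sequence), length(st$sequence) + 1)
  expect_equal(st4$loop_lengths[li], st$loop_lengths[li] + 1L)
  del_pos <- which(!is.na(st4$loop_id) & st4$loop_id == li & st4$loop_pos == slot)
  st5 <- apply_move(st4, structure(list(kind = "delete", position = del_pos,
                                        residue = NA_character_, loop_id = li,
                                        slot = slot),
                                   class = "move_proposal"))
  expect_equal(st5$sequence, st$sequence)
  expect_equal(st5$column_map, st$column_map)
  expect_equal(st5$loop_lengths, st$loop_lengths)

  # conserved positions keep their alignment columns across an insertion
  cons_cols_before <- st$column_map[!is.na(st$column_map)]
  cons_cols_after <- st4$column_map[!is.na(st4$column_map)]
  expect_equal(cons_cols_after, cons_cols_before)
  # and the conserved residues are identical
  expect_equal(st4$sequence[!is.na(st4$column_map)],
               st$sequence[!is.na(st$column_map)])

  # illegal moves rejected
  expect_error(apply_move(st, structure(list(kind = "delete", position = 1,
                                             residue = NA, loop_id = 99),
                                        class = "move_proposal")), "illegal|subscript")
})

test_that("metropolis_accept follows min(1, exp(-delta/T))", {
  # non-positive delta always accepted
  set.seed(5)
  expect_true(all(replicate(100, metropolis_accept(-0.3, 0.5))))
  expect_true(metropolis_accept(0, 1))
  # near-zero temperature rejects uphill moves
  set.seed(6)
  expect_false(any(replicate(100, metropolis_accept(0.5, 1e-9))))
  # empirical acceptance at (delta = 1, T = 1) ~ exp(-1) within 3 sigma
  set.seed(7)
  n <- 1e5
  acc <- mean(replicate(n, metropolis_accept(1, 1)))
  p <- exp(-1)
  expect_lt(abs(acc - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("run_hallucination returns the initial state for zero steps and a non-increasing best envelope", {
  pp <- small_planted(n_random = 50)
  run0 <- run_hallucination(pp$start_sequence, pp$profile, pp$background,
                            pp$predictor, anneal_schedule(n_steps = 0),
                            seed = 1, start_loop_lengths = pp$start_loop_lengths)
  expect_equal(paste(run0$best$sequence, collapse = ""), pp$start_sequence)
  expect_equal(nrow(run0$trajectory), 0)

  run <- run_hallucination(pp$start_sequence, pp$profile, pp$background,
                           pp$predictor, anneal_schedule(0.05, 0.001, 150),
                           seed = 2, start_loop_lengths = pp$start_loop_lengths)
  env <- cummin(run$trajectory$total)
  expect_true(all(diff(env) <= 1e-12))
  expect_lte(run$best$loss$total, min(run$trajectory$total) + 1e-12)
  # frozen identities never change along a trajectory
  froz <- which(!is.na(run$best$column_map))[1:2]
  runf <- run_hallucination(pp$start_sequence, pp$profile, pp$background,
                            pp$predictor, anneal_schedule(0.05, 0.001, 120),
                            seed = 3, start_loop_lengths = pp$start_loop_lengths,
                            frozen = froz)
  st0 <- hallucination_state(pp$start_sequence, pp$profile$annotation,
                             pp$start_loop_lengths, frozen = froz)
  orig <- st0$sequence[froz]
  expect_equal(runf$final$sequence[frozen_positions(runf$final)], orig)
  expect_equal(runf$best$sequence[frozen_positions(runf$best)], orig)
})

test_that("identical seed and inputs give byte-identical trajectories", {
  pp <- small_planted(n_random = 50)
  args <- list(pp$start_sequence, pp$profile, pp$background, pp$predictor,
               anneal_schedule(0.05, 0.001, 100))
  r1 <- do.call(run_hallucination, c(args, list(seed = 42,
                start_loop_lengths = pp$start_loop_lengths)))
  r2 <- do.call(run_hallucination, c(args, list(seed = 42,
                start_loop_lengths = pp$start_loop_lengths)))
  f1 <- tempfile(); f2 <- tempfile()
  write_trajectory(r1, f1); write_trajectory(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(paste(r1$best$sequence, collapse = ""),
                   paste(r2$best$sequence, collapse = ""))
  # different seed, different draw sequence
  r3 <- do.call(run_hallucination, c(args, list(seed = 43,
                start_loop_lengths = pp$start_loop_lengths)))
  expect_false(identical(r1$trajectory$delta, r3$trajectory$delta))
})

test_that("fixed-temperature sampling reproduces the Boltzmann distribution on an enumerable space", {
  # 2 positions x 2 letters, substitution-only: exhaustive partition function
  pp <- small_planted(n_random = 50)
  ab <- c("A", "D")
  ann <- pp$profile$annotation
  # restrict to a 2-conserved-column problem by freezing everything else
  st <- hallucination_state(pp$planted_full, ann, pp$start_loop_lengths)
  cons <- which(!is.na(st$column_map))
  free <- cons[c(2, 5)]
  frozen <- setdiff(cons, free)
  # freeze the loop lengths via zero-width bounds
  ann2 <- ann
  ann2$loop_bounds[, "min"] <- st$loop_lengths
  ann2$loop_bounds[, "max"] <- st$loop_lengths
  # score all 4 states exhaustively
  temp <- 0.15
  seq0 <- st$sequence
  energies <- matrix(NA_real_, 2, 2, dimnames = list(ab, ab))
  cfg <- loss_config()
  for (a in ab) for (b in ab) {
    s <- seq0; s[free[1]] <- a; s[free[2]] <- b
    pred <- predict_geometry(pp$predictor, paste(s, collapse = ""),
                             loop_lengths = st$loop_lengths)
    energies[a, b] <- total_loss(pred, pp$profile, pp$background,
                                 st$column_map, cfg)$total
  }
  Z <- sum(exp(-energies / temp))
  target <- exp(-energies / temp) / Z

  # frozen positions cover everything except the two free ones; alphabet {A,D}
  # makes proposals symmetric
  n_steps <- 4000
  prof2 <- pp$profile
  prof2$annotation <- ann2
  run <- run_hallucination(paste(seq0, collapse = ""), prof2,
                           pp$background, pp$predictor,
                           anneal_schedule(temp, temp, n_steps),
                           move_probs = c(1, 0, 0), cfg = cfg, seed = 11,
                           start_loop_lengths = st$loop_lengths,
                           frozen = frozen, alphabet = ab)
  # reconstruct visited states from the trajectory
  tr <- run$trajectory
  cur <- seq0
  visits <- matrix(0, 2, 2, dimnames = list(ab, ab))
  for (k in seq_len(nrow(tr))) {
    if (tr$accepted[k] && tr$kind[k] == "substitute") {
      cur[tr$position[k]] <- tr$residue[k]
    }
    visits[cur[free[1]], cur[free[2]]] <- visits[cur[free[1]], cur[free[2]]] + 1
  }
  freq <- visits / sum(visits)
  for (a in ab) for (b in ab) {
    p <- target[a, b]
    se <- sqrt(p * (1 - p) / n_steps)
    # correlated samples: allow a generous multiple of the iid binomial error
    expect_lt(abs(freq[a, b] - p), 6 * se + 0.02)
  }
})
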