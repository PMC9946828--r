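test_that("classify_regions applies the gap threshold and segment demotion", {
  # gap-free alignment: all conserved, one segment
  aln <- c(a = "ADKLMQ", b = "ADKLMQ", c = "ADRLMQ")
  ann <- classify_regions(aln)
  expect_equal(ann$column_class, rep("conserved", 6))
  expect_equal(nrow(ann$segments), 1)

  # column gapped in 3/5 members at threshold 0.5 -> variable
  aln2 <- c(a = "ADKLM", b = "AD-LM", c = "AD-LM", d = "AD-LM", e = "ADKLM")
  ann2 <- classify_regions(aln2, gap_threshold = 0.5, min_segment_length = 1)
  expect_equal(ann2$column_class[3], "variable")
  # at threshold 0.6 the same column stays conserved
  ann3 <- classify_regions(aln2, gap_threshold = 0.6, min_segment_length = 1)
  expect_equal(ann3$column_class[3], "conserved")

  # short conserved runs are demoted
  aln4 <- c(a = "AD--K--LMQR", b = "AD--K--LMQR", c = "AD--K--LMQR")
  ann4 <- classify_regions(aln4, gap_threshold = 0.3, min_segment_length = 3)
  expect_equal(ann4$column_class[5], "variable")     # lone conserved column
  expect_equal(ann4$column_class[8:11], rep("conserved", 4))

  expect_error(classify_regions(c(a = "AD", b = "ADK")), "ragged")
  expect_error(classify_regions(c(a = "AD")), ">= 2")
})

test_that("a staggered toy loop of lengths 2/3/3/4 yields bounds (1,5)", {
  # loop block (columns 5-10) staggered so every loop column is gapped in
  # exactly half the members; loop lengths {2,3,3,4} by hand enumeration
  aln <- c(m1 = "ADKL----WEVKNLM",
           m2 = "ADKL-P--WEVKNLM",
           m3 = "ADKLG-AA--VKNLM",
           m4 = "ADKLGPAA--VKNLM")
  lens <- vapply(strsplit(substr(aln, 5, 10), ""), function(x) sum(x != "-"),
                 integer(1))
  expect_equal(unname(lens), c(2, 3, 3, 4))
  ann <- classify_regions(aln, gap_threshold = 0.3, min_segment_length = 3)
  vseg <- ann$segments[ann$segments$type == "variable", ]
  expect_equal(nrow(vseg), 1)
  expect_equal(c(vseg$start, vseg$end), c(5, 10))
  expect_equal(unname(ann$loop_bounds[1, ]), c(1L, 5L))
})

test_that("build_profile pools observed bins and normalizes", {
  spec <- bin_spec()
  bb <- helix_backbone(6, sequence = "ADKLMQ")
  aln <- c(m1 = "ADKLMQ")
  # single member is not a valid alignment for classify_regions; build the
  # annotation from a 2-member copy instead
  aln2 <- c(m1 = "ADKLMQ", m2 = "ADKLMQ")
  ann <- classify_regions(aln2)

  # single structure, eps = 0: every supported pair one-hot
  p1 <- build_profile(list(bb, bb), aln2, ann, spec, pseudocount = 0)
  expect_true(all(abs(rowSums(p1$restraints$d) - 1) < 1e-9))
  expect_true(all(apply(p1$restraints$d, 1, max) == 1))
  expect_true(all(p1$support == 2))

  # two identical structures give the same one-hot result as one
  g <- compute_geometry(reconstruct_cb(bb), spec)
  b12 <- observed_bins(g, 1, 2, spec)
  pr_pair <- which(p1$pairs[, 1] == 1 & p1$pairs[, 2] == 2)
  expect_equal(p1$restraints$d[pr_pair, b12[["d"]]], 1)

  # two structures observing different distance bins -> 0.5/0.5
  bb2 <- bb
  bb2$coords$CB <- bb$coords$CB + 0  # copy
  bb2 <- reconstruct_cb(bb2)
  shifted <- bb
  for (at in names(shifted$coords)) shifted$coords[[at]][6, ] <-
    shifted$coords[[at]][6, ] + c(3, 0, 0)   # move last residue a few bins
  p2 <- build_profile(list(bb, shifted), aln2, ann, spec, pseudocount = 0)
  g2 <- compute_geometry(reconstruct_cb(shifted), spec)
  pr <- which(p2$pairs[, 1] == 1 & p2$pairs[, 2] == 6)
  ba <- observed_bins(g, 1, 6, spec)[["d"]]
  bbb <- observed_bins(g2, 1, 6, spec)[["d"]]
  expect_false(ba == bbb)
  expect_equal(p2$restraints$d[pr, ba], 0.5)
  expect_equal(p2$restraints$d[pr, bbb], 0.5)

  expect_error(build_profile(list(bb), aln2, ann, spec), "differ in number")
  expect_error(build_profile(list(bb, helix_backbone(5, sequence = "ADKLM")),
                             aln2, ann, spec), "non-gap")
})

test_that("profile counts match a naive double-loop recount on a small family", {
  spec <- bin_spec()
  fam <- make_toy_family(toy_family_spec(
    n_members = 4,
    segment_plan = list(list(type = "helix", length = 6),
                        list(type = "loop", length = c(1, 3)),
                        list(type = "strand", length = 5)),
    coordinate_jitter = 0.3, loop_length_seed = 3, jitter_seed = 4))
  prof <- build_profile(fam$structures, fam$alignment, fam$truth, spec,
                        pseudocount = 0)
  # naive recount, written independently: loop over members, conserved column
  # pairs and channels, tally observed bins
  cc <- fam$truth$conserved_cols
  gmaps <- lapply(fam$structures, function(s) compute_geometry(reconstruct_cb(s), spec))
  for (pick in list(c(1, 2), c(3, 9), c(5, 11))) {
    a <- cc[pick[1]]; b <- cc[pick[2]]
    counts <- numeric(n_bins(spec, "d"))
    sup <- 0
    for (m in seq_along(gmaps)) {
      mm <- fam$truth$member_maps[[m]]
      if (is.na(mm[a]) || is.na(mm[b])) next
      bin <- observed_bins(gmaps[[m]], mm[a], mm[b], spec)[["d"]]
      counts[bin] <- counts[bin] + 1
      sup <- sup + 1
    }
    row <- which(prof$pairs[, 1] == a & prof$pairs[, 2] == b)
    expect_equal(prof$support[row], sup)
    expect_equal(prof$restraints$d[row, ], counts / sum(counts))
  }
})

test_that("smoothing is monotone and keeps distributions normalized", {
  spec <- bin_spec()
  bb <- helix_backbone(5, sequence = "ADKLM")
  aln <- c(m1 = "ADKLM", m2 = "ADKLM")
  ann <- classify_regions(aln)
  mins <- vapply(c(0, 1e-4, 1e-2, 1), function(eps) {
    p <- build_profile(list(bb, bb), aln, ann, spec, pseudocount = eps)
    expect_true(all(abs(rowSums(p$restraints$omega) - 1) < 1e-9))
    min(p$restraints$d)
  }, numeric(1))
  expect_true(all(diff(mins) > 0))
})

test_that("profile persistence round-trips and guards its format", {
  spec <- bin_spec()
  # gapped member so the member maps carry NA entries through serialization
  bb <- helix_backbone(5, sequence = "ADKLM")
  bb2 <- helix_backbone(4, sequence = "ADLM")
  aln <- c(m1 = "ADKLM", m2 = "AD-LM")
  prof <- build_profile(list(bb, bb2), aln,
                        classify_regions(aln, gap_threshold = 0.4,
                                         min_segment_length = 1), spec)
  path <- tempfile(fileext = ".json")
  save_profile(prof, path)
  prof2 <- load_profile(path)
  for (ch in names(prof$restraints)) {
    expect_lt(max(abs(prof2$restraints[[ch]] - prof$restraints[[ch]])), 1e-12)
  }
  expect_equal(prof2$pairs, prof$pairs)
  expect_equal(prof2$support, prof$support)
  expect_equal(prof2$spec$edges, prof$spec$edges)
  expect_equal(prof2$annotation$member_maps, prof$annotation$member_maps)
  expect_equal(prof2$annotation$conserved_cols, prof$annotation$conserved_cols)

  # wrong bin count -> corrupt-file error
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$restraints$d <- obj$restraints$d[, 1:5]
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(obj, bad, digits = NA, auto_unbox = TRUE)
  expect_error(load_profile(bad), "wrong bin count")

  # older declared format version -> version-mismatch error
  obj2 <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj2$format_version <- 0
  old <- tempfile(fileext = ".json")
  jsonlite::write_json(obj2, old, digits = NA, auto_unbox = TRUE)
  expect_error(load_profile(old), "version")

  # not a profile at all
  junk <- tempfile(fileext = ".json")
  writeLines("{\"hello\": 1}", junk)
  expect_error(load_profile(junk), "corrupt")
})

test_that("family members are more profile-consistent than random structures", {
  spec <- bin_spec()
  fam <- make_toy_family(toy_family_spec(
    n_members = 4,
    segment_plan = list(list(type = "helix", length = 7),
                        list(type = "loop", length = c(2, 2)),
                        list(type = "strand", length = 6)),
    coordinate_jitter = 0.1))
  prof <- build_profile(fam$structures, fam$alignment, fam$truth, spec)
  cfg <- loss_config()
  member_ce <- function(bb, mm) {
    g <- compute_geometry(reconstruct_cb(bb), spec)
    oh <- geometry_onehot(g, spec)
    cmap <- rep(NA_integer_, g$length)
    cmap[mm[!is.na(mm)]] <- which(!is.na(mm))
    restraint_loss(oh, prof, cmap, cfg)
  }
  ce_member <- member_ce(fam$structures[[1]], fam$truth$member_maps[[1]])
  # a random coil of the same residue count
  set.seed(9)
  n <- length(fam$structures[[1]]$resid)
  tors <- cbind(phi = runif(n, -180, 180), psi = runif(n, -180, 180),
                omega = rep(180, n))
  coil <- build_backbone_from_torsions(tors)
  ce_rand <- member_ce(coil, fam$truth$member_maps[[1]])
  expect_lt(ce_member, ce_rand)
})

test_that("alignment FASTA round-trips", {
  aln <- c(m1 = "ADK-LM", m2 = "ADKGLM")
  path <- tempfile(fileext = ".fasta")
  write_alignment(aln, path)
  expect_equal(toupper(read_alignment(path)), aln)
})
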