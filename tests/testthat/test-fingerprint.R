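test_that("tip-of-loop picks the middle residue, lower of two for even loops", {
  expect_equal(tip_of_loop_index(5), 3L)
  expect_equal(tip_of_loop_index(6), 3L)
  expect_equal(tip_of_loop_index(1), 1L)
  expect_equal(tip_of_loop_index(13), 7L)
  expect_equal(tip_of_loop_index(2), 1L)
  expect_error(tip_of_loop_index(0), "at least one")
})

test_that("TOL centroids sit on the tip CA with weighted properties", {
  spec <- fixture_spec(seed = 21L, jitter = 0)
  tcr <- make_toy_tcr(spec, 1, 1)
  cdrs <- assign_properties(extract_cdrs(tcr$structure, tcr$annotation))
  cen <- place_centroids_tol(cdrs)
  expect_equal(cen$mode, "TOL")
  expect_equal(dim(cen$coords), c(6L, 5L))
  for (loop in rownames(cen$coords)) {
    at <- cdrs$loops[[loop]]
    resnos <- unique(at$residue_number)
    tip <- resnos[tip_of_loop_index(length(resnos))]
    ca <- at[at$residue_number == tip & at$atom_name == "CA", ]
    expect_equal(unname(cen$coords[loop, ]),
                 unname(unlist(ca[1, c("x", "y", "z", "q_w", "l_w")])))
    # the 4th/5th coordinates are C*charge and P*logP of that CA
    expect_equal(cen$coords[loop, "q_w"], 25 * ca$charge[1],
                 ignore_attr = TRUE)
    expect_equal(cen$coords[loop, "l_w"], 4 * ca$logp[1],
                 ignore_attr = TRUE)
  }
  # a tip residue without CA is fatal, naming the loop
  maimed <- cdrs
  at <- maimed$loops$CDR2b
  resnos <- unique(at$residue_number)
  tip <- resnos[tip_of_loop_index(length(resnos))]
  maimed$loops$CDR2b <- at[!(at$residue_number == tip &
                               at$atom_name == "CA"), ]
  expect_error(place_centroids_tol(maimed), "CDR2b")
})

test_that("fingerprint moments match direct formulas on constructed inputs", {
  # all atoms coincident with a centroid -> (0, 0, 0) triple
  atoms <- matrix(rep(c(1, 2, 3, 0.5, -0.2), each = 4), 4, 5)
  cen <- matrix(rep(c(1, 2, 3, 0.5, -0.2), each = 6), 6, 5)
  v <- tcrfp:::es5d_values(atoms, cen)
  expect_equal(unname(v), rep(0, 18))
  # two atoms at distances 1 and 3 from a centroid -> (2, 1, 0)
  atoms2 <- rbind(c(1, 0, 0, 0, 0), c(3, 0, 0, 0, 0))
  cen2 <- matrix(0, 6, 5)
  v2 <- tcrfp:::es5d_values(atoms2, cen2)
  expect_equal(unname(v2[1:3]), c(2, 1, 0))
  # 4-atom configuration vs an independent one-pass moment computation
  set.seed(77)
  atoms4 <- matrix(stats::rnorm(20), 4, 5)
  cen4 <- matrix(stats::rnorm(30), 6, 5)
  got <- tcrfp:::es5d_values(atoms4, cen4)
  for (i in 1:6) {
    d <- apply(atoms4, 1, function(a) sqrt(sum((a - cen4[i, ])^2)))
    m1 <- sum(d) / 4
    m2 <- sum((d - m1)^2) / 4
    m3 <- sum((d - m1)^3) / 4
    expect_equal(unname(got[(3 * i - 2):(3 * i)]),
                 c(m1, sqrt(m2), sign(m3) * abs(m3)^(1 / 3)),
                 tolerance = 1e-9)
  }
  # raw third-moment variant preserves the central moment itself
  raw <- tcrfp:::es5d_values(atoms4, cen4, third_moment = "raw")
  expect_equal(raw[3], sign(got[3]) * abs(got[3])^3, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("fingerprints have 18 finite values with nonnegative mean and SD", {
  sr <- small_repertoire(seed = 31L)
  for (fp in sr$fps) {
    expect_length(fp$values, 18L)
    expect_true(all(is.finite(fp$values)))
    stats_ <- sub(".*\\.", "", names(fp$values))
    expect_true(all(fp$values[stats_ == "mean"] >= 0))
    expect_true(all(fp$values[stats_ == "sd"] >= 0))
  }
})

test_that("similarity follows the Manhattan closed form and its endpoints", {
  sr <- small_repertoire(seed = 13L)
  fp <- sr$fps[[1]]
  expect_identical(fp_similarity(fp, fp), 1)
  # uniform offset of 1 in every entry -> exactly 0.5
  fp2 <- fp
  fp2$values <- fp$values + 1
  expect_identical(fp_similarity(fp, fp2), 0.5)
  # random vectors match an independent recomputation
  set.seed(99)
  for (i in 1:50) {
    a <- fp
    b <- fp
    a$values <- stats::rnorm(18)
    b$values <- stats::rnorm(18)
    expect_equal(fp_similarity(a, b),
                 (1 + sum(abs(a$values - b$values)) / 18)^(-1),
                 tolerance = 1e-12)
    expect_equal(fp_similarity(a, b), fp_similarity(b, a))
    expect_true(fp_similarity(a, b) > 0 && fp_similarity(a, b) <= 1)
  }
})

test_that("fingerprints with differing provenance refuse comparison", {
  sr <- small_repertoire(seed = 17L)
  fp <- sr$fps[[1]]
  other <- sr$fps[[2]]
  other$C <- 35
  expect_error(fp_similarity(fp, other), "incompatible")
  other <- sr$fps[[2]]
  other$hydrogen_policy <- "all-atom"
  expect_error(fp_similarity(fp, other), "incompatible")
  other <- sr$fps[[2]]
  other$table_tag <- "another-table"
  expect_error(fp_similarity(fp, other), "incompatible")
})

test_that("pairwise similarity matrix is consistent with pairwise calls", {
  sr <- small_repertoire(n_families = 2, per_family = 2, seed = 23L)
  fps <- unname(sr$fps)
  sim <- pairwise_similarity(fps)
  expect_equal(diag(sim), rep(1, 4), ignore_attr = TRUE)
  expect_equal(sim, t(sim))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(sim[i, j], fp_similarity(fps[[i]], fps[[j]]))
  }
  # permuting the input permutes rows/columns consistently
  perm <- c(3, 1, 4, 2)
  sim_p <- pairwise_similarity(fps[perm])
  expect_equal(sim_p, sim[perm, perm])
  # duplicate ids are fatal
  expect_error(pairwise_similarity(fps[c(1, 1, 2)]), "duplicate")
  # two identical fingerprints -> all-ones matrix
  dup <- fps[[1]]
  dup$tcr_id <- "copy"
  expect_equal(unname(pairwise_similarity(list(fps[[1]], dup))),
               matrix(1, 2, 2))
})

test_that("TOL fingerprints are invariant under rigid motions", {
  spec <- fixture_spec(seed = 41L)
  tcr <- make_toy_tcr(spec, 1, 1)
  fp0 <- fingerprint_structure(tcr$structure, tcr$annotation)
  set.seed(4)
  for (i in 1:10) {
    moved <- apply_rigid(tcr$structure, random_rotation(),
                         stats::runif(3, -50, 50))
    fp1 <- fingerprint_structure(moved, tcr$annotation)
    expect_equal(fp_similarity(fp0, fp1), 1, tolerance = 1e-9)
  }
})

test_that("coordinate scaling scales mean and SD when 5D weights vanish", {
  # homogeneity of the Euclidean distance in the geometric limit: zero out
  # the charge/lipophilicity dimensions and scale coordinates by lambda
  set.seed(12)
  atoms <- cbind(matrix(stats::rnorm(30), 10, 3), 0, 0)
  cen <- cbind(matrix(stats::rnorm(18), 6, 3), 0, 0)
  lambda <- 2.5
  v1 <- tcrfp:::es5d_values(atoms, cen)
  v2 <- tcrfp:::es5d_values(atoms * lambda, cen * lambda)
  stats_ <- sub(".*\\.", "", names(v1))
  sel <- stats_ %in% c("mean", "sd")
  expect_equal(v2[sel], lambda * v1[sel], tolerance = 1e-9)
})

test_that("fingerprint tables round-trip through disk", {
  sr <- small_repertoire(n_families = 2, per_family = 2, seed = 29L)
  path <- tempfile(fileext = ".tsv")
  write_fingerprints(unname(sr$fps), path)
  back <- read_fingerprints(path)
  expect_length(back, 4L)
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$values, sr$fps[[i]]$values, tolerance = 1e-12)
    expect_equal(back[[i]]$tcr_id, sr$fps[[i]]$tcr_id)
  }
  expect_equal(pairwise_similarity(back), sr$sim, tolerance = 1e-10)
})
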