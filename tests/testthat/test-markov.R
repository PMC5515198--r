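test_that("worked-example cohort gives the enumerated breast-to-bone entry", {
  sites <- c("bone", "chest_wall", "ln_mammary", "ln_distant", "lung_pleura",
             "liver", "brain", "other")
  other_first <- rep(setdiff(sites, "bone"), length.out = 64)
  pw <- c(replicate(36, pathway(list("breast", "bone")), simplify = FALSE),
          lapply(other_first, function(s) pathway(list("breast", s))))
  A <- suppressWarnings(estimate_transition_matrix(pw))
  expect_equal(A$probs["breast", "bone"], 0.36)
  expect_equal(A$counts["breast", "bone"], 36)
  expect_equal(sum(A$counts["breast", ]), 100)
})

test_that("deterministic chains estimate to unit transition probabilities", {
  pw <- replicate(5, pathway(list("breast", "bone", "deceased")),
                  simplify = FALSE)
  A <- suppressWarnings(estimate_transition_matrix(pw))
  expect_equal(A$probs["breast", "bone"], 1)
  expect_equal(A$probs["bone", "deceased"], 1)
  expect_equal(A$probs["deceased", "deceased"], 1)
})

test_that("fractional counts for co-occurring sets match the hand tally", {
  A <- suppressWarnings(estimate_transition_matrix(fixture_pathways()))
  # breast exits: bone 4 (incl. one from the co-occurring pair), liver 2,
  # chest wall 1 -> row 4/7, 2/7, 1/7
  expect_equal(A$counts["breast", c("bone", "liver", "chest_wall")],
               c(bone = 4, liver = 2, chest_wall = 1))
  expect_equal(A$probs["breast", "bone"], 4 / 7)
  # bone exits: lung gets 1 (pw2) + 0.5 (pw4, split over {bone, liver});
  # liver gets 1 (pw3)
  expect_equal(A$counts["bone", "lung_pleura"], 1.5)
  expect_equal(A$counts["bone", "liver"], 1)
  expect_equal(A$probs["bone", c("lung_pleura", "liver")],
               c(lung_pleura = 0.6, liver = 0.4))
  # liver exits: deceased 2 (pw3, pw6), lung 0.5 (pw4)
  expect_equal(A$probs["liver", c("deceased", "lung_pleura")],
               c(deceased = 0.8, lung_pleura = 0.2))
})

test_that("estimation handles smoothing and rejects degenerate input", {
  pw <- list(pathway(list("breast", "bone")))
  expect_warning(A <- estimate_transition_matrix(pw), "self-absorbing")
  expect_equal(A$probs["liver", "liver"], 1)
  A2 <- estimate_transition_matrix(pw, smoothing = "add_one")
  expect_equal(unname(A2$probs["liver", "bone"]), 1 / 9)
  expect_equal(unname(A2$probs["liver", "breast"]), 0)
  expect_error(estimate_transition_matrix(list()), "empty")
  expect_error(estimate_transition_matrix(list(pathway(list("breast")))),
               "beyond the primary")
})

test_that("estimated matrices are row-stochastic with absorbing deceased", {
  for (seed in 1:3) {
    coh <- simulate_cohort(default_config(n_patients = 150, seed = seed))
    A <- suppressWarnings(
      estimate_transition_matrix(extract_pathways(coh)))
    expect_true(all(abs(rowSums(A$probs) - 1) < 1e-9))
    expect_true(all(A$probs >= 0 & A$probs <= 1))
    expect_equal(unname(A$probs["deceased", "deceased"]), 1)
  }
})

test_that("counts equal an exhaustive independent tally on small fixtures", {
  pw <- fixture_pathways()
  # oracle: enumerate every (from-site, to-site) pair transition by brute force
  tax <- met_sites()
  oracle <- matrix(0, length(tax), length(tax), dimnames = list(tax, tax))
  for (p in pw) {
    for (k in seq_len(length(p$steps) - 1)) {
      from <- p$steps[[k]]; to <- p$steps[[k + 1]]
      for (i in from) for (j in to)
        oracle[i, j] <- oracle[i, j] + 1 / length(from)
    }
  }
  A <- suppressWarnings(estimate_transition_matrix(pw))
  expect_equal(A$counts, oracle)
})

test_that("propagation follows v A^k and preserves stochasticity", {
  A <- toy_deterministic_matrix()
  v0 <- state_vector()
  expect_equal(propagate(v0, A, 0), v0)
  v2 <- propagate(v0, A, 2)
  expect_equal(unname(v2["deceased"]), 1)
  # identity matrix leaves any state vector unchanged
  tax <- met_sites()
  I <- structure(list(probs = diag(length(tax)) + 0, counts = diag(length(tax)),
                      taxonomy = tax), class = "transition_matrix")
  dimnames(I$probs) <- list(tax, tax)
  # identity has deceased self-prob 1 already
  v <- state_vector(setNames(rep(0.1, 10), tax))
  expect_equal(propagate(v, I, 5), v)
  # stochasticity along a random chain
  set.seed(77)
  R <- random_transition_matrix()
  for (k in c(1, 3, 7))
    expect_equal(sum(propagate(v0, R, k)), 1, tolerance = 1e-9)
  expect_error(propagate(state_vector(taxonomy = c("breast", "deceased"),
                                      probs = c(breast = 1, deceased = 0)),
                         R, 1), "taxonom")
})

test_that("deceased mass is non-decreasing under propagation", {
  set.seed(123)
  for (rep in 1:5) {
    A <- random_transition_matrix()
    v0 <- state_vector()
    mass <- vapply(0:12, function(k)
      propagate(v0, A, k)[["deceased"]], numeric(1))
    expect_true(all(diff(mass) >= -1e-12))
  }
})

test_that("estimation recovers a known matrix from simulated pathways", {
  cfg <- default_config(n_patients = 5000, seed = 2024,
                        multiplicity = c(1, 0, 0),
                        censoring = list(min = 100, max = 100))
  coh <- simulate_cohort(cfg)
  pw <- extract_pathways(coh, window_years = 100)
  A <- suppressWarnings(estimate_transition_matrix(pw))
  truth <- Reduce(`+`, Map(`*`, cfg$subgroup_proportions,
                           cfg$transition_matrices))
  exits <- rowSums(A$counts)
  for (s in names(exits)[exits >= 200]) {
    expect_lt(max(abs(A$probs[s, ] - truth[s, ])), 0.03)
  }
  expect_gt(sum(exits >= 200), 5)
})

test_that("conditional next-step distributions match hand counts", {
  pw <- list(pathway(list("breast", "bone", "lung_pleura")),
             pathway(list("breast", "bone", "lung_pleura", "liver")),
             pathway(list("breast", "bone", "liver")),
             pathway(list("breast", "bone", "deceased")),
             pathway(list("breast", "bone")),
             pathway(list("breast", "liver")))
  # 2 of the 4 continuing breast-bone pathways go to lung
  res <- conditional_next_distribution(pw, c("breast", "bone"))
  expect_equal(res$n_matched, 5L)
  expect_equal(res$n_continued, 4L)
  expect_equal(res$distribution[["lung_pleura"]], 0.5)
  expect_equal(res$distribution[["liver"]], 0.25)
  # prefix (breast) reproduces the estimated breast row on singleton firsts
  res2 <- conditional_next_distribution(pw, "breast")
  A <- suppressWarnings(estimate_transition_matrix(pw))
  expect_equal(res2$distribution[["bone"]],
               unname(A$probs["breast", "bone"]))
  # no match is an empty distribution, not an error
  res3 <- conditional_next_distribution(pw, c("breast", "brain"))
  expect_equal(res3$n_matched, 0L)
  expect_length(res3$distribution, 0L)
  expect_error(conditional_next_distribution(pw, c("bone")), "breast")
})

test_that("after breast-bone-lung the chain favours liver over death", {
  # follow-up long enough that censoring cannot bias the next-step mix
  coh <- simulate_cohort(default_config(n_patients = 3000, seed = 321,
                                        censoring = list(min = 60,
                                                         max = 60)))
  pw <- extract_pathways(coh, window_years = 60)
  res <- conditional_next_distribution(pw,
                                       c("breast", "bone", "lung_pleura"))
  expect_gt(res$n_continued, 20)
  expect_equal(names(res$distribution)[1], "liver")
  expect_lt(res$distribution[["deceased"]], res$distribution[["liver"]])
})

test_that("transition matrices round-trip through csv and json", {
  set.seed(5)
  A <- random_transition_matrix()
  cf <- withr::local_tempfile(fileext = ".csv")
  jf <- withr::local_tempfile(fileext = ".json")
  write_transition_matrix(A, cf, "csv")
  write_transition_matrix(A, jf, "json")
  expect_equal(read_transition_matrix(cf, "csv")$probs, A$probs)
  back <- read_transition_matrix(jf, "json")
  expect_equal(back$probs, A$probs)
  expect_equal(back$counts, A$counts)
})
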