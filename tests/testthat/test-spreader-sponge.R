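test_that("two-step pathway probabilities are products of matrix entries", {
  A <- toy_deterministic_matrix()
  A$probs["bone", ] <- 0
  A$probs["bone", "liver"] <- 0.6
  A$probs["bone", "deceased"] <- 0.4
  res <- enumerate_two_step_pathways(A, top_n = "all")
  nz <- res$pathways[res$pathways$probability > 0, ]
  expect_equal(nrow(nz), 2L)
  expect_equal(nz$probability, c(0.6, 0.4))
  expect_equal(nz$intermediate, c("bone", "bone"))
  expect_equal(nz$terminal, c("liver", "deceased"))
  expect_equal(res$coverage, 100)
  top1 <- enumerate_two_step_pathways(A, top_n = 1)
  expect_equal(top1$coverage, 60)
  expect_error(enumerate_two_step_pathways(A, top_n = 0), "positive")

  set.seed(31)
  R <- random_transition_matrix()
  res2 <- enumerate_two_step_pathways(R, top_n = "all")
  for (r in sample(nrow(res2$pathways), 20)) {
    row <- res2$pathways[r, ]
    expect_equal(row$probability,
                 R$probs["breast", row$intermediate] *
                   R$probs[row$intermediate, row$terminal])
  }
  expect_equal(res2$coverage, 100)
  # descending order with deterministic ties
  expect_true(all(diff(res2$pathways$probability) <= 1e-15))
})

test_that("classification agrees with a brute-force double loop", {
  set.seed(202)
  for (rep in 1:5) {
    R <- random_transition_matrix()
    cls <- classify_sites(R)
    oracle <- brute_force_masses(R$probs)
    expect_equal(setNames(cls$table$outgoing, cls$table$site),
                 oracle$outgoing)
    expect_equal(setNames(cls$table$incoming, cls$table$site),
                 oracle$incoming)
    fac <- oracle$outgoing / oracle$incoming
    expect_equal(setNames(cls$table$factor, cls$table$site), fac)
    expect_equal(cls$table$label,
                 unname(ifelse(fac > 1, "spreader",
                               "sponge")[cls$table$site]))
  }
})

test_that("symmetric flows are neutral and zero inflow is flagged", {
  tax <- met_sites()
  sites <- setdiff(tax, c("breast", "deceased"))
  A <- matrix(0, length(tax), length(tax), dimnames = list(tax, tax))
  A["breast", sites] <- 1 / length(sites)
  for (s in sites) A[s, sites] <- 1 / length(sites)  # doubly symmetric block
  A["deceased", "deceased"] <- 1
  S <- structure(list(probs = A, counts = A, taxonomy = tax),
                 class = "transition_matrix")
  cls <- classify_sites(S)
  expect_true(all(cls$table$label == "neutral"))
  expect_true(all(abs(cls$table$factor - 1) <= 1e-12))

  # bone gets outflow from breast but no inflow: flagged, not labelled
  B <- matrix(0, length(tax), length(tax), dimnames = list(tax, tax))
  B["breast", "bone"] <- 0.6; B["breast", "liver"] <- 0.4
  B["bone", "liver"] <- 1; B["liver", "deceased"] <- 1
  for (s in setdiff(sites, c("bone", "liver"))) B[s, "deceased"] <- 1
  B["deceased", "deceased"] <- 1
  SB <- structure(list(probs = B, counts = B, taxonomy = tax),
                  class = "transition_matrix")
  cls2 <- classify_sites(SB)
  tab <- cls2$table
  expect_equal(tab$label[tab$site == "bone"], "undefined")
  expect_equal(tab$outgoing[tab$site == "bone"], 0.6)
  expect_equal(tab$incoming[tab$site == "bone"], 0)
  # liver: outgoing 0.4 * 1, incoming 0.6 * 1 from bone -> sponge
  expect_equal(tab$outgoing[tab$site == "liver"], 0.4)
  expect_equal(tab$incoming[tab$site == "liver"], 0.6)
  expect_equal(tab$label[tab$site == "liver"], "sponge")
})

test_that("labels are scale-invariant and masses conserve total flow", {
  set.seed(44)
  R <- random_transition_matrix()
  cls <- classify_sites(R)
  # conservation: incoming over terminals + mass ending in breast/deceased
  # equals total two-step mass = sum of breast-row mass over intermediates
  res <- enumerate_two_step_pathways(R, top_n = "all")
  total <- sum(res$pathways$probability)
  sites <- setdiff(R$taxonomy, c("breast", "deceased"))
  into_terminal <- sum(res$pathways$probability[
    res$pathways$terminal %in% c("breast", "deceased")])
  expect_equal(sum(cls$table$incoming) + into_terminal, total)
  expect_equal(total, sum(R$probs["breast", sites]))
  # scaling the breast row scales both masses, leaving factors unchanged
  R2 <- R
  R2$probs["breast", ] <- R2$probs["breast", ] / 2
  R2$probs["breast", "deceased"] <-
    R2$probs["breast", "deceased"] + 0.5
  cls2 <- classify_sites(R2)
  expect_equal(cls2$table$factor, cls$table$factor)
  expect_equal(cls2$table$label, cls$table$label)
})

test_that("default synthetic chain labels bone spreader and liver sponge", {
  coh <- simulate_cohort(default_config(seed = 17))
  fit <- metachain_fit(coh)
  cls <- classify_sites(fit$transition)
  tab <- cls$table
  expect_equal(tab$label[tab$site == "bone"], "spreader")
  expect_equal(tab$label[tab$site == "liver"], "sponge")
  # the most probable sponge destination when exiting bone is lung/pleura
  ex <- site_exit_distribution(fit$transition, "bone", top_k = 9)
  sponges <- tab$site[tab$label == "sponge"]
  met_dest <- ex$distribution[setdiff(names(ex$distribution), "deceased")]
  expect_equal(names(which.max(met_dest[sponges[sponges %in% names(met_dest)]])),
               "lung_pleura")
})

test_that("one-step mode uses off-diagonal row and column sums", {
  set.seed(9)
  R <- random_transition_matrix()
  cls <- classify_sites(R, mode = "one_step")
  tab <- cls$table
  for (s in tab$site) {
    expect_equal(tab$outgoing[tab$site == s],
                 sum(R$probs[s, ]) - R$probs[s, s])
    expect_equal(tab$incoming[tab$site == s],
                 sum(R$probs[, s]) - R$probs[s, s])
  }
})

test_that("exit distributions truncate rows with retained mass reported", {
  A <- toy_deterministic_matrix()
  ex <- site_exit_distribution(A, "bone", top_k = 3)
  expect_equal(ex$distribution[["deceased"]], 1)
  expect_equal(ex$retained_pct, 100)
  set.seed(3)
  R <- random_transition_matrix()
  row <- sort(R$probs["bone", ], decreasing = TRUE)
  ex2 <- site_exit_distribution(R, "bone", top_k = 2)
  expect_equal(unname(ex2$distribution), unname(row[1:2]))
  expect_equal(ex2$retained_pct, 100 * sum(row[1:2]))
  expect_error(site_exit_distribution(R, "deceased"), "absorbing")
})

test_that("chord and classification exports are well formed", {
  set.seed(12)
  R <- random_transition_matrix()
  jf <- withr::local_tempfile(fileext = ".json")
  chord <- export_chord(R, jf)
  doc <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(doc$nodes, R$taxonomy)
  expect_equal(nrow(doc$links), sum(R$probs > 0))
  i <- 7
  expect_equal(doc$links$probability[i],
               R$probs[doc$links$source[i], doc$links$target[i]])
  cf <- withr::local_tempfile(fileext = ".json")
  export_classification(classify_sites(R), cf)
  cdoc <- jsonlite::read_json(cf, simplifyVector = TRUE)
  expect_equal(cdoc$mode, "two_step")
  expect_setequal(names(cdoc$sites),
                  c("site", "outgoing", "incoming", "factor", "label"))
})
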