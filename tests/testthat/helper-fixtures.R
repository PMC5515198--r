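# fixtures built in code: small cohorts and pathway lists reused across tests

make_patients <- function(ids, vital = "alive", followup = 12,
                          er = "positive", her2 = "negative") {
  data.frame(patient_id = ids,
             er_status = rep_len(er, length(ids)),
             her2_status = rep_len(her2, length(ids)),
             vital_status = rep_len(vital, length(ids)),
             followup_years = rep_len(followup, length(ids)))
}

# cohort of 5 patients with mixed subgroups, censoring and a death
fixture_cohort <- function() {
  pts <- data.frame(
    patient_id = c("p1", "p2", "p3", "p4", "p5"),
    er_status = c("positive", "negative", "positive", "negative", "unknown"),
    her2_status = c("negative", "negative", "positive", "positive", "unknown"),
    vital_status = c("alive", "deceased", "alive", "deceased", "alive"),
    followup_years = c(12, 4, 15, 11, 6))
  ev <- data.frame(
    patient_id = c("p1", "p2", "p2", "p3", "p3", "p3", "p4"),
    site = c("bone", "bone", "liver", "bone", "liver", "lung_pleura", "brain"),
    time = c(3.0, 2.0, 3.1, 1.0, 1.0, 6.0, 9.5))
  metacohort(pts, ev)
}

# pathway list used for hand-tallied estimation checks: 6 pathways, one with
# a co-occurring pair
fixture_pathways <- function() {
  list(
    pathway(list("breast", "bone")),
    pathway(list("breast", "bone", "lung_pleura")),
    pathway(list("breast", "bone", "liver", "deceased")),
    pathway(list("breast", c("bone", "liver"), "lung_pleura")),
    pathway(list("breast", "chest_wall")),
    pathway(list("breast", "liver", "deceased")))
}

# deterministic 3-state toy chain over the full taxonomy:
# breast -> bone -> deceased with probability 1
toy_deterministic_matrix <- function() {
  tax <- met_sites()
  A <- matrix(0, length(tax), length(tax), dimnames = list(tax, tax))
  A["breast", "bone"] <- 1
  A["bone", "deceased"] <- 1
  for (s in setdiff(tax, c("breast", "bone")))
    A[s, "deceased"] <- 1
  A["deceased", ] <- 0; A["deceased", "deceased"] <- 1
  structure(list(probs = A, counts = A, taxonomy = tax),
            class = "transition_matrix")
}

# random row-stochastic transition matrix respecting the structural rules
# (deceased absorbing, breast column zero)
random_transition_matrix <- function() {
  tax <- met_sites()
  n <- length(tax)
  A <- matrix(stats::rgamma(n * n, shape = 1), n, n,
              dimnames = list(tax, tax))
  A[, "breast"] <- 0
  A["breast", "deceased"] <- 0
  A <- A / rowSums(A)
  A["deceased", ] <- 0; A["deceased", "deceased"] <- 1
  structure(list(probs = A, counts = A * 50, taxonomy = tax),
            class = "transition_matrix")
}

# brute-force double loop over all (i, j): independent oracle for two-step
# spreader/sponge masses
brute_force_masses <- function(P) {
  tax <- rownames(P)
  sites <- setdiff(tax, c("breast", "deceased"))
  outgoing <- sapply(sites, function(s) {
    tot <- 0
    for (j in tax) tot <- tot + P["breast", s] * P[s, j]
    tot
  })
  incoming <- sapply(sites, function(s) {
    tot <- 0
    for (i in sites) tot <- tot + P["breast", i] * P[i, s]
    tot
  })
  list(outgoing = outgoing, incoming = incoming)
}
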