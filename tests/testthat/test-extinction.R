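test_that("iucn_scenario orders threat categories and spares DD/domesticated", {
  net <- host_parasite_network(
    data.frame(parasite = "P", host = c("A", "B", "C", "D", "E")),
    data.frame(host = c("A", "B", "C", "D", "E"),
               iucn_status = c("CR", "EN", "LC", "EN", "DD"),
               domesticated = c(FALSE, FALSE, FALSE, TRUE, FALSE),
               extinct = FALSE))
  sc <- suppressMessages(iucn_scenario(net))
  expect_equal(sc$provenance, "iucn_ordered")
  expect_equal(sc$events$CR, "A")
  expect_equal(sc$events$EN, "B")     # D is domesticated EN -> treated LC
  expect_equal(sc$events$VU, character(0))
  expect_equal(sc$events$NT, character(0))
  expect_false("E" %in% unlist(sc$events))  # DD never removed

  all_lc <- host_parasite_network(
    data.frame(parasite = "P", host = "A"),
    data.frame(host = "A", iucn_status = "LC",
               domesticated = FALSE, extinct = FALSE))
  expect_message(sc2 <- iucn_scenario(all_lc), "empty threat categories")
  expect_true(all(lengths(sc2$events) == 0))
})

test_that("random_order_scenario is seed-deterministic and uniform", {
  fx <- fixture_fig1()
  s1 <- random_order_scenario(fx$net, "Pc", seed = 7)
  s2 <- random_order_scenario(fx$net, "Pc", seed = 7)
  expect_identical(s1$events, s2$events)
  expect_equal(sort(unlist(s1$events)), c("A", "B", "C"))
  expect_true(all(lengths(s1$events) == 1))

  expect_equal(sort(unlist(
    random_order_scenario(fx$net, "Pc", exclusions = "A", seed = 1)$events)),
    c("B", "C"))
  expect_error(
    random_order_scenario(fx$net, "Pc", exclusions = c("A", "B", "C"),
                          seed = 1),
    "no eligible hosts")

  # each of the 6 permutations of 3 hosts appears with frequency 1/6
  # within 3 sigma over 6000 seeded draws
  perms <- vapply(1:6000, function(s)
    paste(unlist(random_order_scenario(fx$net, "Pc", seed = s)$events),
          collapse = ""),
    character(1))
  freq <- table(perms) / 6000
  expect_equal(length(freq), 6)
  sigma <- sqrt((1 / 6) * (5 / 6) / 6000)
  expect_true(all(abs(freq - 1 / 6) < 3 * sigma))
})

test_that("scenario construction rejects overlapping events", {
  expect_error(extinction_scenario(list(c("A", "B"), c("B"))), "disjoint")
})

test_that("run_scenario reproduces the hand-computed MPD sequence", {
  fx <- fixture_fig1()
  sc <- extinction_scenario(list("C", "B"))
  tj <- run_scenario(sc, fx$net, fx$tree)
  pd <- tj$steps[tj$steps$parasite == "Pd", ]
  expect_equal(pd$mpd, c(14 / 3, 2, 0), tolerance = 1e-12)
  expect_equal(pd$delta_mpd, c(0, 2 - 14 / 3, -14 / 3), tolerance = 1e-12)
  expect_equal(pd$host_richness, c(3, 2, 1))
  expect_equal(pd$state, rep("extant", 3))
  # the specialist on C coextincts at step 1
  pa <- tj$steps[tj$steps$parasite == "Pa", ]
  expect_equal(pa$state, c("extant", "coextinct", "coextinct"))
  expect_equal(tj$newly_coextinct[[2]], "Pa")

  # obligate multi-host rule: richness < 2 means coextinct
  tj2 <- run_scenario(sc, fx$net, fx$tree,
                      rule = coextinction_rule("min_hosts_k", k = 2))
  pd2 <- tj2$steps[tj2$steps$parasite == "Pd", ]
  expect_equal(pd2$state, c("extant", "extant", "coextinct"))

  # empty scenario: a single baseline step
  tj3 <- run_scenario(extinction_scenario(list()), fx$net, fx$tree)
  expect_equal(length(unique(tj3$steps$step)), 1)
  expect_equal(tj3$steps$mpd[tj3$steps$parasite == "Pc"], 14 / 3,
               tolerance = 1e-12)
})

test_that("trajectory invariants hold on random scenarios", {
  set.seed(101)
  for (i in 1:20) {
    tr <- ape::rphylo(sample(8:25, 1), 1, 0.2)
    net <- random_network(tr, sample(4:12, 1))
    pool <- sample(tr$tip.label, sample(2:length(tr$tip.label), 1))
    nev <- sample(1:min(4, length(pool)), 1)
    cuts <- sort(sample(seq_along(pool), nev - 1))
    events <- unname(split(pool, findInterval(seq_along(pool), cuts + 1)))
    sc <- extinction_scenario(events)
    rule <- if (runif(1) < 0.5) coextinction_rule("all_hosts_lost") else
      coextinction_rule("min_hosts_k", k = sample(1:3, 1))
    tj <- run_scenario(sc, net, tr, rule)
    st <- tj$steps
    for (p in unique(st$parasite)) {
      sp <- st[st$parasite == p, ]
      sp <- sp[order(sp$step), ]
      expect_true(all(diff(sp$host_richness) <= 0))
      # coextinct state never reverts
      expect_true(all(diff(sp$state == "coextinct") >= 0))
    }
    # all_hosts_lost: coextinct at a step <=> zero surviving richness,
    # against a direct set-intersection oracle
    if (rule$mode == "all_hosts_lost") {
      surv <- network_hosts(net)
      for (s in 0:length(sc$events)) {
        if (s > 0) surv <- setdiff(surv, sc$events[[s]])
        sub <- st[st$step == s, ]
        for (p in sub$parasite) {
          oracle_rich <- length(intersect(net$assoc[[p]], surv))
          expect_equal(sub$host_richness[sub$parasite == p], oracle_rich)
          expect_equal(sub$state[sub$parasite == p] == "coextinct",
                       oracle_rich == 0)
        }
      }
    }
  }
})

test_that("same seed gives identical trajectories; MPD paths both rise and fall", {
  fx <- fixture_fig1()
  t1 <- run_scenario(random_order_scenario(fx$net, "Pd", seed = 5),
                     fx$net, fx$tree)
  t2 <- run_scenario(random_order_scenario(fx$net, "Pd", seed = 5),
                     fx$net, fx$tree)
  expect_identical(t1$steps, t2$steps)

  deltas <- vapply(1:20, function(s) {
    tj <- run_scenario(random_order_scenario(fx$net, "Pd", seed = s),
                       fx$net, fx$tree)
    d <- tj$steps$delta_mpd[tj$steps$parasite == "Pd" & tj$steps$step == 1]
    d
  }, numeric(1))
  expect_true(any(deltas > 1e-9))   # losing B first: 14/3 -> 6
  expect_true(any(deltas < -1e-9))  # losing C first: 14/3 -> 2
})

test_that("classify_outcome reproduces the four single-loss outcomes", {
  fx <- fixture_fig1()
  for (i in seq_len(nrow(fx$cases))) {
    cs <- fx$cases[i, ]
    out <- classify_outcome(fx$net, fx$tree, cs$lost_host)
    expect_equal(unname(out[cs$parasite]), cs$expected_outcome)
  }
  out <- classify_outcome(fx$net, fx$tree, "C")
  expect_equal(unname(out["Pb"]), "unaffected")  # Pb has hosts {A,B}
  # partition: every parasite gets exactly one known label
  expect_true(all(out %in% c("coextinction", "reduced_to_single_host",
                             "mpd_decrease", "mpd_increase", "unchanged",
                             "unaffected")))
  expect_setequal(names(out), network_parasites(fx$net))
  expect_error(classify_outcome(fx$net, fx$tree, "Z"), "unknown host")

  # labels agree with direct before/after MPD recomputation on random nets
  set.seed(111)
  for (i in 1:5) {
    tr <- ape::rphylo(10, 1, 0)
    net <- random_network(tr, 8)
    lost <- sample(tr$tip.label, 1)
    out <- classify_outcome(net, tr, lost)
    surv <- setdiff(tr$tip.label, lost)
    for (p in names(out)) {
      doc <- net$assoc[[p]]
      if (!lost %in% doc) { expect_equal(unname(out[p]), "unaffected"); next }
      if (length(doc) == 1) { expect_equal(unname(out[p]), "coextinction"); next }
      if (length(doc) == 2) {
        expect_equal(unname(out[p]), "reduced_to_single_host"); next
      }
      d <- oracle_mpd(tr, intersect(doc, surv)) - oracle_mpd(tr, doc)
      expected <- if (abs(d) <= 1e-9) "unchanged" else
        if (d < 0) "mpd_decrease" else "mpd_increase"
      expect_equal(unname(out[p]), expected)
    }
  }
})

test_that("ed_shift follows gain = ed_extant - ed_full with non-negative gains", {
  tr <- toy_tree()
  sh <- ed_shift(tr, "B")
  expect_equal(sh$ed_full[sh$tip == "A"], 2)
  expect_equal(sh$ed_extant[sh$tip == "A"], 3)
  expect_equal(sh$gain[sh$tip == "A"], 1)
  expect_equal(sh$gain[sh$tip == "C"], 0)
  expect_true(is.na(sh$gain[sh$tip == "B"]))

  sh0 <- ed_shift(tr)
  expect_true(all(sh0$gain == 0))
  expect_error(ed_shift(tr, c("A", "B", "C")), "no survivors")
  expect_error(ed_shift(tr, "Z"), "not in tree")

  set.seed(121)
  bt <- ape::rphylo(50, 1, 0.3)
  ext <- sample(bt$tip.label, 15)
  sh2 <- ed_shift(bt, ext)
  surv <- !sh2$tip %in% ext
  expect_true(all(sh2$gain[surv] >= -1e-9))
  expect_true(all(is.na(sh2$gain[!surv])))
})

test_that("delta_mpd_projection keeps LC/DD hosts and flags coextinctions", {
  tr <- toy_tree()
  net <- host_parasite_network(
    data.frame(parasite = c("P1", "P1", "P1", "P2"),
               host = c("A", "B", "C", "B")),
    data.frame(host = c("A", "B", "C"),
               iucn_status = c("LC", "EN", "LC"),
               domesticated = FALSE, extinct = FALSE))
  pr <- delta_mpd_projection(net, tr)
  expect_equal(pr$mpd_now[pr$parasite == "P1"], 14 / 3, tolerance = 1e-12)
  expect_equal(pr$mpd_after[pr$parasite == "P1"], 6)  # d(A, C)
  expect_equal(pr$state[pr$parasite == "P2"], "coextinct")
  expect_true(is.na(pr$mpd_after[pr$parasite == "P2"]))

  # all hosts LC: projection is the identity
  all_lc <- host_parasite_network(
    data.frame(parasite = c("P1", "P1", "P1"), host = c("A", "B", "C")),
    data.frame(host = c("A", "B", "C"), iucn_status = "LC",
               domesticated = FALSE, extinct = FALSE))
  pr2 <- delta_mpd_projection(all_lc, tr)
  expect_equal(pr2$mpd_after, pr2$mpd_now, tolerance = 1e-12)
})

test_that("missing hosts error by default and can be dropped explicitly", {
  tr <- toy_tree()
  net <- host_parasite_network(
    data.frame(parasite = c("P1", "P1", "P2"), host = c("A", "Z", "Z")),
    data.frame(host = c("A", "Z"), iucn_status = "LC",
               domesticated = FALSE, extinct = FALSE))
  sc <- extinction_scenario(list("A"))
  expect_error(run_scenario(sc, net, tr), "missing from tree: Z")
  expect_message(net2 <- drop_missing_hosts(net, tr), "dropping")
  expect_equal(network_parasites(net2), "P1")
  expect_equal(net2$assoc$P1, "A")
})
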