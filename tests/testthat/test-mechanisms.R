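test_that("phi coefficient matches the 2x2 contingency oracle", {
  # perfect coupling: x at i exactly when y at j
  a <- make_aln(c("RE", "RE", "DK", "DK"))
  expect_equal(pair_phi(a, 1, 2, "R", "E"), 1)
  # perfect anti-coupling: x at i exactly when y NOT at j
  expect_equal(pair_phi(a, 1, 2, "R", "K"), -1)
  # constant indicator -> 0 by convention
  expect_equal(pair_phi(a, 1, 2, "W", "E"), 0)

  # 6-sequence hand example against the direct 2x2 computation
  b <- make_aln(c("RE", "RD", "DE", "DD", "RE", "DD"))
  for (x in c("R", "D")) {
    for (y in c("E", "D")) {
      expect_equal(pair_phi(b, 1, 2, x, y),
                   oracle_phi(b$mat[, 1] == x, b$mat[, 2] == y),
                   tolerance = 1e-12)
    }
  }
})

test_that("transition scores combine phis as favor-minus-disfavor", {
  a <- make_aln(c("RE", "RE", "DR", "DR"))
  # phi(R,E) = phi(D,R) = 1, cross pairs phi = -1 -> PT = 4
  expect_equal(transition_score(a, 1, 2, "R", "E", "D", "R"), 4)
  # symmetric under swapping the two pairs
  expect_equal(transition_score(a, 1, 2, "D", "R", "R", "E"), 4)

  spec <- synthetic_spec(n_seq = 150, n_col = 6,
                         planted_pairs = list(planted_pair(2, 4, "charge_swap")),
                         noise = 0, seed = 4)
  aln <- generate_alignment(spec)
  # exhaustive check: the generative transition scores highest among all
  # transitions between residue pairs observed at the planted positions
  xs <- unique(aln$mat[, 2])
  ys <- unique(aln$mat[, 4])
  best <- -Inf
  for (x in xs) for (y in ys) for (p in xs) for (q in ys) {
    if (x == p && y == q) next
    best <- max(best, transition_score(aln, 2, 4, x, y, p, q))
  }
  expect_equal(transition_score(aln, 2, 4, "R", "E", "D", "R"), best)
})

test_that("the classifier reproduces the worked size/hbond/charge examples", {
  expect_equal(classify_transition("I", "A", "V", "V"), "size")
  expect_equal(classify_transition("A", "P", "S", "S"), "hbond")
  expect_equal(classify_transition("R", "E", "D", "R"), "charge")
})

test_that("classification respects the fixed priority order", {
  # charge beats size: RE -> DK swaps signs AND compensates volume
  ann <- residue_annotations()
  expect_gte(ann["K", "volume"] - ann["E", "volume"], 18)
  expect_lte(ann["D", "volume"] - ann["R", "volume"], -18)
  expect_equal(classify_transition("R", "E", "D", "K"), "charge")

  # charge beats cation-pi: KE -> FK has cross pair (x=K, b=K) like-charged
  expect_equal(classify_transition("K", "E", "F", "K"), "charge")

  # cation-pi beats pi-pi: RF -> FF
  expect_equal(classify_transition("R", "F", "F", "F"), "cation_pi")

  # size beats hbond: SQ -> WA is both a double volume swap and an hbond loss
  expect_gte(ann["W", "volume"] - ann["S", "volume"], 18)
  expect_lte(ann["A", "volume"] - ann["Q", "volume"], -18)
  expect_equal(classify_transition("S", "Q", "W", "A"), "size")

  # hbond beats the residual classes: ST -> AG loses a donor/acceptor pair
  expect_equal(classify_transition("S", "T", "A", "G"), "hbond")

  # residual hydropathy classes
  expect_equal(classify_transition("A", "L", "V", "I"), "other_hydrophobic")
  expect_equal(classify_transition("S", "T", "N", "Q"), "other_hydrophilic")
  expect_equal(classify_transition("A", "S", "A", "T"), "other_mixed")
})

test_that("classification is symmetric in pairs and positions", {
  set.seed(59)
  res <- rownames(residue_annotations())
  for (rep in 1:200) {
    q <- sample(res, 4, replace = TRUE)
    if (identical(q[1:2], q[3:4])) next
    m <- classify_transition(q[1], q[2], q[3], q[4])
    expect_equal(classify_transition(q[3], q[4], q[1], q[2]), m)
    expect_equal(classify_transition(q[2], q[1], q[4], q[3]), m)
  }
})

test_that("charge class covers sign swaps, discharges and avoided like charges", {
  expect_equal(classify_transition("R", "E", "A", "V"), "charge")  # discharge
  expect_equal(classify_transition("A", "V", "K", "D"), "charge")  # symmetric
  # avoid-like-charges via cross pair y/a: (x=A, y=K) -> (a=K, b=G)
  expect_equal(classify_transition("A", "K", "K", "G"), "charge")
  # same-sign pair without opposite charges or cross conflict is not charge
  expect_false(classify_transition("K", "K", "A", "V") == "charge")
})

test_that("top transitions rank by PT with deterministic tie-break", {
  # exactly two observed residue pairs -> a single candidate transition
  a <- make_aln(c("RE", "RE", "DR", "DR"))
  tr <- top_transitions(a, pair_set(rbind(c(1, 2)), 1:2))
  expect_equal(nrow(tr), 1)
  expect_equal(tr$mechanism, "charge")
  expect_equal(tr$score, 4)
  expect_equal(paste0(tr$from_x, tr$from_y, tr$to_a, tr$to_b), "DRRE")

  # n larger than the candidate count returns all candidates
  b <- make_aln(c("RE", "DR", "KD", "KD"))
  trb <- top_transitions(b, pair_set(rbind(c(1, 2)), 1:2), n = 100)
  expect_equal(nrow(trb), choose(3, 2))

  # a monomorphic pair yields no records
  c_ <- make_aln(c("AARE", "AARE", "AADR", "AADR"))
  trc <- top_transitions(c_, pair_set(rbind(c(1, 2), c(3, 4)), 1:4))
  expect_setequal(unique(paste(trc$i, trc$j)), "3 4")

  # planted generative transition ranks first
  spec <- synthetic_spec(n_seq = 300, n_col = 10,
                         planted_pairs = list(planted_pair(3, 8, "size_comp")),
                         noise = 0.03, seed = 21)
  aln <- generate_alignment(spec)
  tr2 <- top_transitions(aln, pair_set(rbind(c(3, 8)), 1:10))
  expect_equal(paste0(tr2$from_x[1], tr2$from_y[1], "-",
                      tr2$to_a[1], tr2$to_b[1]), "IA-VV")
})

test_that("clean planted couplings recover their generating mechanism", {
  target <- c(charge_swap = "charge", size_comp = "size", hbond = "hbond")
  for (mech in names(target)) {
    hits <- 0
    for (s in 1:10) {
      spec <- synthetic_spec(n_seq = 150, n_col = 8,
                             planted_pairs = list(planted_pair(2, 6, mech)),
                             noise = 0, seed = 300 + s)
      tr <- top_transitions(generate_alignment(spec),
                            pair_set(rbind(c(2, 6)), 1:8))
      if (identical(pair_mechanisms(tr)$mechanism, unname(target[mech]))) {
        hits <- hits + 1
      }
    }
    expect_equal(hits, 10)
  }
})

test_that("mechanism distributions and per-class overlap follow the formulas", {
  rec <- data.frame(i = rep(1, 4), j = rep(2, 4),
                    from_x = "A", from_y = "A", to_a = "V", to_b = "V",
                    score = 1,
                    mechanism = c("charge", "charge", "charge", "size"))
  d <- mechanism_distribution(rec)
  expect_equal(unname(d["charge"]), 0.75)
  expect_equal(unname(d["size"]), 0.25)
  expect_equal(sum(d), 1)
  expect_error(mechanism_distribution(rec[0, ]), "no transition")

  mk_rec <- function(i, j, mech) {
    data.frame(i = i, j = j, from_x = "A", from_y = "A", to_a = "V",
               to_b = "V", score = 1, mechanism = mech)
  }
  a <- rbind(mk_rec(1, 2, "charge"), mk_rec(3, 4, "size"),
             mk_rec(5, 6, "size"))
  b <- rbind(mk_rec(1, 2, "charge"), mk_rec(3, 4, "size"),
             mk_rec(7, 8, "size"))
  ov <- mechanism_overlap(a, b)
  expect_equal(unname(ov["charge"]), 100)
  expect_equal(unname(ov["size"]), 50)    # A=2, B=2, C=1
  expect_true(is.na(ov["hbond"]))         # absent from both -> undefined
  ov_same <- mechanism_overlap(a, a)
  expect_equal(unname(ov_same[c("charge", "size")]), c(100, 100))
  ov_disj <- mechanism_overlap(mk_rec(1, 2, "charge"), mk_rec(3, 4, "charge"))
  expect_equal(unname(ov_disj["charge"]), 0)

  # majority with priority tie-break: 1 charge + 1 size at one pair -> charge
  tie <- rbind(mk_rec(1, 2, "size"), mk_rec(1, 2, "charge"))
  expect_equal(pair_mechanisms(tie)$mechanism, "charge")
})
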