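test_that("identical sequences align gap-free at 100% identity", {
  set.seed(3)
  a <- random_aa(80)
  aln <- global_align(a, a)
  expect_equal(aln$identity_pct, 100)
  expect_equal(aln$aligned_a, a)
  expect_equal(aln$aligned_b, a)
})

test_that("aligning an empty sequence is an error", {
  expect_error(global_align("AAAA", ""), class = "coralox_type_error")
})

test_that("exhaustive alignment enumeration validates the DP oracle", {
  # the enumeration oracle walks every gapped alignment; the Gotoh DP oracle
  # must agree with it before it is trusted on longer pairs
  set.seed(41)
  for (k in 1:30) {
    a <- random_nt(sample(2:4, 1))
    b <- random_nt(sample(2:4, 1))
    expect_equal(oracle_gotoh(a, b), oracle_enum_align(a, b))
  }
})

test_that("global alignment scores match the independent DP oracle", {
  set.seed(43)
  for (k in 1:60) {
    a <- random_nt(sample(2:8, 1))
    b <- random_nt(sample(2:8, 1))
    expect_equal(global_align(a, b)$score, oracle_gotoh(a, b))
  }
})

test_that("alignment score is symmetric under a symmetric matrix", {
  set.seed(47)
  for (k in 1:10) {
    a <- random_aa(sample(20:60, 1))
    b <- random_aa(sample(20:60, 1))
    expect_equal(global_align(a, b)$score, global_align(b, a)$score)
  }
})

test_that("identity uses the configured denominator", {
  aln <- global_align("AAAA", "AAAT")
  expect_equal(aln$identity_pct, 75)
  # shorter-sequence denominator
  p <- align_params(identity_denominator = "shorter")
  a <- paste0(strrep("M", 10), "WLLAKHHHNI")
  aln2 <- global_align(a, "WLLAKHHHNI", p)
  expect_equal(aln2$identity_pct, 100)
})

test_that("reference positions map to themselves in a self-alignment", {
  set.seed(53)
  ref <- random_aa(1066)
  aln <- global_align(ref, ref)
  for (pos in c(757L, 762L, 943L, 947L, 1066L)) {
    m <- map_position(aln, pos)
    expect_equal(m$status, "mapped")
    expect_equal(m$query_pos, pos)
  }
  expect_error(map_position(aln, 1067L), class = "coralox_bounds_error")
})

test_that("a query deletion shifts mapped positions by the gap width", {
  set.seed(59)
  ref <- random_aa(300)
  query <- paste0(substr(ref, 1, 100), substr(ref, 111, 300))
  aln <- global_align(ref, query)
  m <- map_position(aln, 200L)
  expect_equal(m$status, "mapped")
  expect_equal(m$query_pos, 190L)
  # a position inside the deleted block is unaligned
  mid <- map_position(aln, 105L)
  expect_equal(mid$status, "unaligned")
})

test_that("positions beyond a fragment's aligned extent are truncated", {
  set.seed(61)
  ref <- random_aa(1066)
  frag <- substr(ref, 400, 1066)
  aln <- global_align(ref, frag)
  expect_equal(map_position(aln, 66L)$status, "truncated")
  expect_equal(map_position(aln, 500L)$status, "mapped")
})

test_that("mapping is strictly monotone over mapped reference positions", {
  set.seed(67)
  ref <- random_aa(200)
  # query with a deletion and some substitutions
  q <- strsplit(paste0(substr(ref, 1, 80), substr(ref, 101, 200)), "")[[1]]
  idx <- sample(length(q), 15)
  q[idx] <- vapply(q[idx], function(r) sample(setdiff(AA20, r), 1), "")
  aln <- global_align(ref, paste(q, collapse = ""))
  mapped <- vapply(1:200, function(p) {
    m <- map_position(aln, p)
    if (m$status == "mapped") m$query_pos else NA_integer_
  }, integer(1))
  expect_true(all(diff(mapped[!is.na(mapped)]) > 0))
})

test_that("rule checks on the reference itself all match at their own positions", {
  cfg <- synth_config(seed = 42)
  ref <- make_pseudo_reference(cfg)
  rules <- residue_rules(coffa_pos = 780)
  lox <- check_rules(ref, ref, rules[rules$domain == "LOX", ])
  expect_true(all(lox$status == "match"))
  expect_equal(lox$query_pos, lox$ref_pos)
})

test_that("planted substitutions and truncations are recovered as such", {
  cfg <- synth_config(seed = 42)
  ref <- make_pseudo_reference(cfg)
  rules <- residue_rules(coffa_pos = 780)
  lox_rules <- rules[rules$domain == "LOX", ]

  x <- strsplit(ref$residues, "")[[1]]
  x[757] <- "K"   # His -> Lys at the first iron ligand
  mut <- paste(x, collapse = "")
  ck <- check_rules(mut, ref, lox_rules)
  expect_equal(ck$status[ck$ref_pos == 757], "substitution")
  expect_equal(ck$observed[ck$ref_pos == 757], "K")
  expect_true(all(ck$status[ck$ref_pos != 757] == "match"))

  trunc <- substr(ref$residues, 1, 940)
  ck2 <- check_rules(trunc, ref, lox_rules)
  expect_true(all(ck2$status[ck2$ref_pos %in% c(943, 947, 1066)] == "truncated"))
  expect_true(all(ck2$status[ck2$ref_pos %in% c(757, 762, 780)] == "match"))
})

test_that("the Coffa determinant maps Gly to R, Ala to S, others indeterminate", {
  expect_equal(coffa_call("G"), "R")
  expect_equal(coffa_call("A"), "S")
  expect_equal(coffa_call(c("I", "F", "V")), rep("indeterminate", 3))
  expect_equal(coffa_call(NA_character_), "indeterminate")
  ck <- data.frame(role = "coffa", observed = "G", stringsAsFactors = FALSE)
  expect_equal(coffa_call(ck), "R")
})

test_that("activity prediction requires every iron ligand and the C-terminal residue", {
  cfg <- synth_config(seed = 42)
  ref <- make_pseudo_reference(cfg)
  rules <- residue_rules(coffa_pos = 780)
  lox_rules <- rules[rules$domain == "LOX", ]

  ok <- check_rules(ref, ref, lox_rules)
  expect_true(predict_activity(ok)$active)

  x <- strsplit(ref$residues, "")[[1]]
  x[757] <- "K"
  bad <- predict_activity(check_rules(paste(x, collapse = ""), ref, lox_rules))
  expect_false(bad$active)
  expect_match(bad$failures, "iron_ligand@757", all = FALSE)

  # fragment missing the C-terminus: cterm check truncated -> inactive
  frag <- substr(ref$residues, 1, 1000)
  noct <- predict_activity(check_rules(frag, ref, lox_rules))
  expect_false(noct$active)
  expect_match(noct$failures, "cterm@1066 truncated", all = FALSE)

  # missing required coverage is a contract error
  expect_error(predict_activity(ok[ok$role == "coffa", , drop = FALSE]),
               class = "coralox_contract_error")
})
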