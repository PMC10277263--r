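test_that("local alignment handles the self and embedded cases", {
  set.seed(51)
  s <- random_protein(50)
  pa <- align_pair(s, s)
  expect_equal(pa$n_identities, 50L)
  expect_equal(pa$n_columns, 50L)
  expect_equal(pa$query_span, c(1L, 50L))

  pa2 <- align_pair("MKV", "AAAMKVAAA")
  expect_equal(pa2$aligned_query, "MKV")
  expect_equal(pa2$n_identities, 3L)

  expect_error(align_pair("", "MKV"), "empty")
  expect_error(align_params(gap_open = 0), "positive")
})

test_that("alignment score matches exhaustive enumeration on short pairs", {
  mat <- blosum62()
  set.seed(53)
  for (r in 1:40) {
    q <- random_protein(sample(1:6, 1), c("A", "C", "D", "E"))
    t <- random_protein(sample(1:6, 1), c("A", "C", "D", "E"))
    expect_equal(align_pair(q, t)$score, oracle_local_score(q, t, mat),
                 info = paste(q, t))
  }
})

test_that("identity and coverage follow their definitions", {
  set.seed(55)
  s <- random_protein(50)
  ic <- identity_and_coverage(align_pair(s, s), 50)
  expect_equal(unname(ic), c(100, 100))

  # 70 identities over 100 columns is 70% identity, gap columns included
  fake <- structure(list(query_id = "q", target_id = "t",
                         aligned_query = "x", aligned_target = "x",
                         score = 0, n_columns = 100L, n_identities = 70L,
                         query_span = c(1L, 90L)),
                    class = "pairwise_alignment")
  expect_equal(identity_and_coverage(fake, 100)[["identity_pct"]], 70)

  # covering query 101..480 of a 480-mer falls below the 80% threshold
  fake$query_span <- c(101L, 480L)
  cov <- identity_and_coverage(fake, 480)[["coverage_pct"]]
  expect_equal(cov, 100 * 380 / 480, tolerance = 1e-12)
  expect_lt(cov, 80)
  expect_error(identity_and_coverage(fake, 0), "positive")
})

test_that("presence calls react to identity as designed", {
  set.seed(57)
  query <- random_protein(200)
  # exact copy: present
  prot <- data.frame(id = "hit", description = "", residues = query,
                     stringsAsFactors = FALSE)
  expect_true(call_presence(query, prot)$present)

  # unrelated random proteome: absent
  rand <- data.frame(id = paste0("r", 1:5), description = "",
                     residues = replicate(5, random_protein(200)),
                     stringsAsFactors = FALSE)
  expect_false(call_presence(query, rand)$present)

  # empty proteome
  empty <- call_presence(query, prot[0, ])
  expect_false(empty$present)
  expect_true(is.na(empty$best_target_id))

  # mutate to a designed identity, ends kept intact so the span is full:
  # 65% is below the rule, 75% above it
  mutate_to <- function(q, ident) {
    chars <- strsplit(q, "")[[1]]
    k <- round((1 - ident) * length(chars))
    pos <- sample(11:(length(chars) - 10), k)
    chars[pos] <- vapply(chars[pos], function(c0)
      sample(setdiff(AA20_H, c0), 1), "")
    paste(chars, collapse = "")
  }
  lo <- data.frame(id = "lo", description = "",
                   residues = mutate_to(query, 0.65), stringsAsFactors = FALSE)
  hi <- data.frame(id = "hi", description = "",
                   residues = mutate_to(query, 0.75), stringsAsFactors = FALSE)
  expect_false(call_presence(query, lo)$present)
  expect_true(call_presence(query, hi)$present)
})

test_that("presence is monotone in the thresholds", {
  set.seed(59)
  query <- random_protein(150)
  chars <- strsplit(query, "")[[1]]
  pos <- sample(6:145, 30)
  chars[pos] <- vapply(chars[pos], function(c0)
    sample(setdiff(AA20_H, c0), 1), "")
  prot <- data.frame(id = "t", description = "",
                     residues = paste(chars, collapse = ""),
                     stringsAsFactors = FALSE)
  loose <- call_presence(query, prot, presence_thresholds(50, 50))
  strict <- call_presence(query, prot, presence_thresholds(95, 99))
  expect_true(loose$present)
  expect_false(strict$present)
})

test_that("profiles recover designed presence and are order invariant", {
  set.seed(61)
  query <- random_protein(150)
  mk_prot <- function(with_hit) {
    dec <- make_decoys(3, lengths = 120:122, query = query)
    if (with_hit) rbind(data.frame(id = "fam", description = "",
                                   residues = query, stringsAsFactors = FALSE),
                        dec) else dec
  }
  seeded <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE)
  prots <- lapply(seeded, mk_prot)
  names(prots) <- paste0("p", 1:10)
  prof <- build_profile(data.frame(id = "q", residues = query), prots)
  expect_equal(prof$present, seeded)

  perm <- sample(10)
  prof2 <- build_profile(data.frame(id = "q", residues = query), prots[perm])
  expect_equal(prof2$present, seeded[perm])
  expect_equal(prof2[match(prof$proteome_id, prof2$proteome_id), "present"],
               prof$present)

  dup <- prots[c(1, 1)]
  expect_error(build_profile(query, dup), "duplicate proteome")
})

test_that("taxon summaries group, sort by absences and conserve totals", {
  prof <- data.frame(
    proteome_id = c("f1", "f2", "p1"),
    present = c(FALSE, FALSE, TRUE), stringsAsFactors = FALSE)
  tax <- data.frame(
    taxon_id = c("f1", "f2", "p1"),
    lineage = c("Eukaryota;Fungi", "Eukaryota;Fungi", "Eukaryota;Plants"),
    stringsAsFactors = FALSE)
  tax$ranks <- strsplit(tax$lineage, ";")
  s <- summarize_by_taxon(prof, tax, rank = 2)
  expect_equal(s$group, c("Fungi", "Plants", "total"))
  expect_equal(s$n_absent, c(2L, 0L, 2L))
  expect_equal(s$n_present, c(0L, 1L, 1L))
  expect_equal(s$n_present[3] + s$n_absent[3], nrow(prof))

  expect_error(summarize_by_taxon(
    data.frame(proteome_id = "zz", present = TRUE), tax), "zz")
})

test_that("distribution statistics average the present calls", {
  prof <- data.frame(proteome_id = c("a", "b", "c"),
                     present = c(TRUE, TRUE, FALSE),
                     identity_pct = c(50, 70, 99),
                     target_length = c(400L, 500L, 10L))
  st <- distribution_stats(prof)
  expect_equal(unname(st["mean_identity_pct"]), 60)
  expect_equal(unname(st["mean_length"]), 450)

  one <- distribution_stats(prof[2, ])
  expect_equal(unname(one["mean_identity_pct"]), 70)

  expect_error(distribution_stats(prof[3, ]), "no present calls")
})
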