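small_cfg <- function(...) {
  sim_config(n_leaves = 6L, root_length = 120L, decoys_per_proteome = 2L,
             implants = list(
               list(motif_name = "CC", text = "CC", position = 10L,
                    protected = TRUE),
               list(motif_name = "CSSC", text = "CSSC", position = 40L,
                    protected = TRUE),
               list(motif_name = "starDEL", text = "KDEL", position = 80L,
                    protected = TRUE)),
             ...)
}

test_that("the zero-mutation limit reproduces the root everywhere", {
  cfg <- small_cfg(seed = 101, subst_prob_per_branch = 0, indel_rate = 0)
  sim <- simulate_family(cfg)
  expect_true(all(sim$family$residues == sim$truth$root_sequence))
  expect_true(all(sim$truth$identity$identity_to_root == 1))
  # the scanner finds every implant in every leaf
  catg <- motif_catalog()
  for (i in seq_len(nrow(sim$truth$leaf_states))) {
    ls <- sim$truth$leaf_states[i, ]
    h <- scan_sequence(sim$family$residues[sim$family$id == ls$leaf],
                       catg[[ls$motif]], ls$leaf)
    expect_true(any(h$start == ls$start & h$matched_text == ls$text))
  }
})

test_that("identical configs and seeds give identical simulations", {
  cfg <- small_cfg(seed = 103)
  s1 <- simulate_family(cfg)
  s2 <- simulate_family(cfg)
  expect_identical(s1$family, s2$family)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_identical(s1$proteomes, s2$proteomes)
  s3 <- simulate_family(small_cfg(seed = 104))
  expect_false(identical(s1$family$residues, s3$family$residues))
})

test_that("protected implants survive any mutation rate at known positions", {
  cfg <- small_cfg(seed = 105, subst_prob_per_branch = 0.3, indel_rate = 1.5)
  sim <- simulate_family(cfg)
  catg <- motif_catalog()
  for (i in seq_len(nrow(sim$truth$leaf_states))) {
    ls <- sim$truth$leaf_states[i, ]
    h <- scan_sequence(sim$family$residues[sim$family$id == ls$leaf],
                       catg[[ls$motif]], ls$leaf)
    expect_true(any(h$start == ls$start & h$matched_text == ls$text),
                info = paste(ls$leaf, ls$motif))
  }
})

test_that("designed switches change exactly the designated subtree", {
  nwk <- "((A,B)nAB,((C,D)nCD,(E,F)nEF)nCDEF);"
  cfg <- sim_config(seed = 107, tree_mode = "fixed_newick", newick = nwk,
                    root_length = 120L, decoys_per_proteome = 0L,
                    subst_prob_per_branch = 0.05, indel_rate = 0,
                    implants = list(list(motif_name = "CSSC", text = "CSSC",
                                         position = 40L, protected = TRUE)),
                    switches = list(list(motif_name = "CSSC", branch = "nEF",
                                         new_text = "CSSS")))
  sim <- simulate_family(cfg)
  ls <- sim$truth$leaf_states
  expect_setequal(ls$leaf[ls$switched], c("E", "F"))
  expect_equal(unique(ls$text[ls$switched]), "CSSS")
  expect_equal(unique(ls$text[!ls$switched]), "CSSC")

  expect_error(simulate_family(sim_config(
    seed = 1, tree_mode = "fixed_newick", newick = nwk,
    switches = list(list(motif_name = "CSSC", branch = "nope",
                         new_text = "CSSS")),
    implants = list(list(motif_name = "CSSC", text = "CSSC",
                         position = 40L, protected = TRUE)))),
    "unknown branch")
})

test_that("realized identity tracks the closed-form expectation", {
  # fixed balanced tree: every leaf is 2 branches from the root
  nwk <- "((A,B),(C,D));"
  p <- subst_prob_for_identity(0.8, 2)
  expect_equal(expected_identity(p, 2), 0.8, tolerance = 1e-12)
  ids <- c()
  for (s in 1:12) {
    cfg <- sim_config(seed = 200 + s, tree_mode = "fixed_newick",
                      newick = nwk, root_length = 300L,
                      decoys_per_proteome = 0L, indel_rate = 0,
                      subst_prob_per_branch = p, implants = list())
    ids <- c(ids, simulate_family(cfg)$truth$identity$identity_to_root)
  }
  expect_equal(mean(ids), 0.8, tolerance = 0.03)
})

test_that("mean identity decreases as the substitution rate rises", {
  mean_id <- function(p) {
    cfg <- sim_config(seed = 111, tree_mode = "fixed_newick",
                      newick = "((A,B),(C,D));", root_length = 200L,
                      decoys_per_proteome = 0L, indel_rate = 0,
                      subst_prob_per_branch = p, implants = list())
    mean(simulate_family(cfg)$truth$identity$identity_to_root)
  }
  ids <- vapply(c(0, 0.05, 0.15, 0.3), mean_id, 0)
  expect_true(all(diff(ids) < 0))
})

test_that("decoys are deterministic, composition-plausible and never hits", {
  set.seed(121)
  q <- random_protein(150)
  expect_equal(nrow(make_decoys(0)), 0L)
  d1 <- make_decoys(5, lengths = 140:144, query = q, seed = 9)
  d2 <- make_decoys(5, lengths = 140:144, query = q, seed = 9)
  expect_identical(d1, d2)
  for (i in 1:5) {
    pa <- align_pair(q, d1$residues[i])
    ic <- identity_and_coverage(pa, nchar(q))
    expect_false(ic[["identity_pct"]] >= 70 && ic[["coverage_pct"]] > 80)
  }
})

test_that("absent leaves yield absent calls; the rest are recovered", {
  cfg <- small_cfg(seed = 123, absent_leaves = c("t2", "t5"),
                   subst_prob_per_branch = subst_prob_for_identity(0.9, 4),
                   indel_rate = 0.3)
  sim <- simulate_family(cfg)
  prof <- build_profile(
    data.frame(id = "root", residues = sim$truth$root_sequence),
    sim$proteomes)
  got <- prof$present[match(sim$truth$presence$proteome_id,
                            prof$proteome_id)]
  expect_equal(got, sim$truth$presence$present)
})

test_that("simulations write and re-read consistently", {
  cfg <- small_cfg(seed = 125)
  sim <- simulate_family(cfg)
  dir <- tempfile()
  write_simulation(sim, dir)
  fam <- read_fasta(file.path(dir, "family.fasta"))
  expect_equal(fam$residues, sim$family$residues)
  tr <- read_newick(file.path(dir, "tree.nwk"))
  expect_setequal(tr$tip.label, sim$tree$tip.label)
  tx <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_equal(tx$taxon_id, sim$taxonomy$taxon_id)
  expect_equal(length(list.files(file.path(dir, "proteomes"))),
               length(sim$proteomes))
})

test_that("the synthetic master alignment realizes its designed structure", {
  ms <- simulate_master_alignment(n_rows = 40, ref_length = 200,
                                  n_invariant = 12, n_invariant_his = 3,
                                  target_identity = 0.6, gaps_per_row = 4,
                                  seed = 17)
  expect_equal(invariant_columns(ms$aln), ms$truth$invariant_columns)
  expect_equal(invariant_residue_census(ms$aln, "H"), 3L)
  lens <- nchar(gsub("-", "", ms$aln$rows))
  expect_true(all(lens == 200))
})
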