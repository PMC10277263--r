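test_that("column profiles follow the logo information-content math", {
  # zero-entropy column at large n approaches log2(20)
  big <- aln_matrix(setNames(rep("C", 5000), paste0("r", 1:5000)))
  expect_equal(column_profiles(big)$info_bits, log2(20),
               tolerance = 1e-3)

  # the small-sample correction at n = 129
  n129 <- aln_matrix(setNames(rep("C", 129), paste0("r", 1:129)))
  expect_equal(column_profiles(n129)$info_bits,
               log2(20) - 19 / (2 * log(2) * 129), tolerance = 1e-12)

  # uniform over 20 residues at n = 20 clips to zero
  uni <- aln_matrix(setNames(AA20_H, paste0("r", 1:20)))
  p <- column_profiles(uni)
  expect_equal(p$info_bits, 0)
  expect_equal(p$entropy_bits, log2(20))

  # all-gap column carries no information
  gaps <- aln_matrix(c(a = "-M", b = "-M"))
  expect_equal(column_profiles(gaps)$info_bits[1], 0)
  expect_equal(column_profiles(gaps)$n_nongap, c(0L, 2L))
})

test_that("column frequencies and entropies stay within their bounds", {
  set.seed(21)
  for (r in 1:5) {
    rows <- replicate(8, paste(sample(c(AA20_H, "-"), 40, replace = TRUE),
                               collapse = ""))
    a <- aln_matrix(setNames(rows, paste0("s", 1:8)))
    p <- column_profiles(a)
    expect_true(all(p$n_nongap + p$gap_count == a$n_rows))
    expect_true(all(p$entropy_bits >= 0 & p$entropy_bits <= log2(20) + 1e-12))
    expect_true(all(p$info_bits >= 0 & p$info_bits <= log2(20)))
    f_sums <- vapply(seq_len(nrow(p)), function(i) {
      if (p$n_nongap[i] == 0) 1 else sum(p$counts[[i]]) / p$n_nongap[i]
    }, 0)
    expect_equal(f_sums, rep(1, nrow(p)))
  }
})

test_that("invariant columns require full agreement and zero gaps", {
  a <- aln_matrix(c(a = "MC-", b = "MCA", c = "MCC"))
  expect_equal(invariant_columns(a), c(1L, 2L))

  allgap <- aln_matrix(c(a = "---", b = "MCA"))
  expect_equal(length(invariant_columns(allgap)), 0L)

  # brute-force cross-check on random alignments
  set.seed(31)
  for (r in 1:10) {
    rows <- replicate(10, paste(sample(c("A", "C", "-"), 50, replace = TRUE,
                                       prob = c(.45, .45, .1)),
                                collapse = ""))
    a <- aln_matrix(setNames(rows, paste0("s", 1:10)))
    chars <- do.call(rbind, strsplit(rows, ""))
    brute <- which(vapply(seq_len(50), function(j) {
      col <- chars[, j]
      !any(col == "-") && all(col == col[1])
    }, TRUE))
    expect_equal(invariant_columns(a), brute)
  }
})

test_that("the invariant-residue census partitions the invariant columns", {
  a <- aln_matrix(c(a = "MHCH", b = "MHCH", c = "MHCH"))
  expect_equal(invariant_residue_census(a, "H"), 2L)
  expect_equal(invariant_residue_census(a, "W"), 0L)
  total <- sum(vapply(AA20_H, function(r) invariant_residue_census(a, r), 0L))
  expect_equal(total, length(invariant_columns(a)))

  # restriction to a column subset (e.g. structure-resolved positions)
  expect_equal(invariant_residue_census(a, "H", columns = 1:2), 1L)
})

test_that("sequence/column coordinate maps are a bijection off the gaps", {
  a <- aln_matrix(c(a = "M-KV", b = "MAKV"))
  expect_equal(map_seq_to_column(a, "a", 2L), 3L)
  expect_true(is.na(map_column_to_seq(a, "a", 2L)))
  expect_equal(map_column_to_seq(a, "a", 3L), 2L)
  expect_error(map_seq_to_column(a, "a", 4L), "out of range")
  expect_error(map_column_to_seq(a, "a", 5L), "out of range")

  set.seed(41)
  for (r in 1:5) {
    row <- paste(sample(c(AA20_H, "-"), 60, replace = TRUE), collapse = "")
    a <- aln_matrix(c(x = row, y = paste(rep("A", 60), collapse = "")))
    npos <- nchar(gsub("-", "", row))
    if (npos == 0) next
    cols <- map_seq_to_column(a, "x", seq_len(npos))
    expect_equal(map_column_to_seq(a, "x", cols), seq_len(npos))
  }
})

test_that("motif occupancy calls canonical, variant and absent rows", {
  mk <- function(motif) paste0("AAAAG", motif, "GAAAA")
  rows <- c(r1 = mk("CSSC"), r2 = mk("CSSC"), r3 = mk("CSSC"),
            r4 = mk("CSSS"), r5 = mk("AAAA"))
  a <- aln_matrix(rows)
  occ <- motif_occupancy_matrix(a, motif_catalog()["CSSC"])
  occ <- occ[order(occ$seq_id), ]
  expect_equal(occ$status, c("canonical", "canonical", "canonical",
                             "variant", "absent"))
  expect_equal(occ$observed[occ$seq_id == "r4"], "CSSS")
  expect_equal(occ$distance[occ$seq_id == "r4"], 1L)
  expect_equal(unique(occ$anchor_start_col), 6L)
  expect_equal(unique(occ$anchor_end_col), 9L)

  # all rows carrying KDEL at one anchor are all canonical
  rows2 <- setNames(rep(mk("KDEL"), 4), paste0("s", 1:4))
  occ2 <- motif_occupancy_matrix(aln_matrix(rows2), motif_catalog()["starDEL"])
  expect_equal(occ2$status, rep("canonical", 4))

  expect_error(motif_occupancy_matrix(a, list()), "empty")
})

test_that("occupancy of identical rows is constant and row-order invariant", {
  mk <- function(motif) paste0("CAAAG", motif, "GA-AA")
  rows <- c(r1 = mk("KDEL"), r2 = mk("KDEL"), r3 = mk("KDEL"))
  occ <- motif_occupancy_matrix(aln_matrix(rows), motif_catalog()["starDEL"])
  expect_equal(length(unique(occ$status)), 1L)

  rows_mixed <- c(r1 = mk("KDEL"), r2 = mk("KDEI"), r3 = mk("KDEL"),
                  r4 = mk("KDEL"))
  a1 <- motif_occupancy_matrix(aln_matrix(rows_mixed),
                               motif_catalog()["starDEL"])
  a2 <- motif_occupancy_matrix(aln_matrix(rev(rows_mixed)),
                               motif_catalog()["starDEL"])
  a2 <- a2[match(a1$seq_id, a2$seq_id), ]
  rownames(a2) <- NULL
  expect_equal(a1, a2)
  expect_equal(a1$status[a1$seq_id == "r2"], "variant")
})

test_that("coexisting CC and CxxC anchors are reported independently", {
  # one clade carries CC, the other CxxC, at the same N-terminal region
  mkCC <- "AAACCAAGGA"
  mkCx <- "AAACSSCAGG"
  rows <- c(x1 = mkCC, x2 = mkCC, y1 = mkCx, y2 = mkCx)
  occ <- motif_occupancy_matrix(aln_matrix(rows), motif_catalog()[c("CC", "CxxC")])
  cc <- occ[occ$pattern_name == "CC", ]
  cx <- occ[occ$pattern_name == "CxxC", ]
  expect_equal(sort(cc$seq_id[cc$status == "canonical"]), c("x1", "x2"))
  expect_equal(sort(cx$seq_id[cx$status == "canonical"]), c("y1", "y2"))
})

test_that("logo stack heights are frequencies scaled by information", {
  a <- aln_matrix(c(a = "CA", b = "CA", c = "CT", d = "CT"))
  lh <- logo_heights(column_profiles(a))
  c1 <- lh[lh$column == 1, ]
  expect_equal(c1$height, log2(20) - 19 / (2 * log(2) * 4), tolerance = 1e-12)
  c2 <- lh[lh$column == 2, ]
  expect_equal(sum(c2$height), column_profiles(a)$info_bits[2])
  expect_equal(c2$height[1], c2$height[2])
})
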