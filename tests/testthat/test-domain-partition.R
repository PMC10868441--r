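# PAE / disorder-track domain partitioning and protein classification.

test_that("load_pae symmetrizes, clips, and reads both dialects", {
  M <- matrix(8, 3, 3)
  M[1, 2] <- 4; M[2, 1] <- 6
  p <- load_pae(M)
  expect_equal(p$values[1, 2], 5)
  expect_equal(p$values, t(p$values))

  jf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(list(predicted_aligned_error = M)), jf,
                       digits = NA)
  pj <- load_pae(jf)
  expect_equal(nrow(pj$values), 3)
  expect_equal(pj$values[1, 2], 5)

  cf <- withr::local_tempfile(fileext = ".csv")
  write.table(M, cf, sep = ",", row.names = FALSE, col.names = FALSE)
  pc <- load_pae(cf)
  expect_equal(pc$values, pj$values)

  expect_warning(load_pae(matrix(40, 2, 2)), "clipped")
  expect_error(load_pae(matrix(1, 2, 3)), "not square")
})

test_that("mean long-range PAE excludes the near-diagonal band", {
  expect_equal(mean_pae_disorder(matrix(7, 30, 30)), 7)
  N <- 60
  sep <- abs(outer(1:N, 1:N, "-"))
  M <- ifelse(sep < 10, 3, 20)
  expect_equal(mean_pae_disorder(M), 20)
  expect_error(mean_pae_disorder(matrix(1, 5, 5)), "shorter")
})

test_that("uniform PAE extremes give a full-chain domain or none", {
  all_low <- partition_pae(synthetic_pae(80, list(c(1, 80)), noise_sd = 0.3,
                                         seed = 50))
  expect_equal(length(all_low$domains), 1)
  expect_equal(all_low$domains[[1]], c(1, 80))
  expect_equal(all_low$protein_class, "F")

  all_high <- partition_pae(synthetic_pae(80, list(), noise_sd = 0.3,
                                          seed = 51))
  expect_equal(length(all_high$domains), 0)
  expect_equal(all_high$protein_class, "D")
})

test_that("planted two-block PAE is recovered within 3 residues", {
  pae <- synthetic_pae(300, list(c(30, 120), c(160, 280)), seed = 52)
  p <- partition_pae(pae)
  expect_equal(length(p$domains), 2)
  expect_lte(max(abs(p$domains[[1]] - c(30, 120))), 3)
  expect_lte(max(abs(p$domains[[2]] - c(160, 280))), 3)
  expect_equal(p$protein_class, "Mf")
  expect_equal(length(p$linkers), 1)
})

test_that("classification follows the terminal-IDR rules", {
  mk <- function(doms, N) {
    p <- partition_pae(synthetic_pae(N, doms, seed = 53))
    p$protein_class
  }
  expect_equal(mk(list(c(1, 196)), 320), "Sf")    # long C-terminal IDR
  expect_equal(mk(list(c(1, 95)), 100), "F")      # tail below 10 residues
  part <- structure(list(domains = list(c(12, 90)), N = 100),
                    class = "domain_partition")
  expect_equal(classify(part, 100), "Sf")         # N-terminal IDR >= 10
  part$domains <- list(c(5, 95))  # both tails under 10 residues
  expect_equal(classify(part, 100), "F")
})

test_that("disorder tracks partition by ordered runs with gap merging", {
  all_ord <- partition_disorder_track(rep(0.05, 60))
  expect_equal(all_ord$protein_class, "F")
  expect_equal(all_ord$domains[[1]], c(1, 60))

  sc <- c(rep(0.05, 50), rep(0.9, 30), rep(0.05, 50))
  p2 <- partition_disorder_track(sc)
  expect_equal(length(p2$domains), 2)
  expect_equal(p2$protein_class, "Mf")

  # two ordered runs separated by a 2-residue gap merge into one domain
  sc3 <- c(rep(0.05, 30), rep(0.9, 2), rep(0.05, 30))
  p3 <- partition_disorder_track(sc3)
  expect_equal(length(p3$domains), 1)
  expect_equal(p3$domains[[1]], c(1, 62))

  # CheZOD-style: ordered when score above threshold
  chez <- c(rep(12, 40), rep(2, 20), rep(12, 40))
  p4 <- partition_disorder_track(chez, threshold = 8,
                                 ordered_when = "above")
  expect_equal(length(p4$domains), 2)

  # strict inequality: a constant track at the threshold is disordered
  p5 <- partition_disorder_track(rep(0.15, 60), threshold = 0.15)
  expect_equal(p5$protein_class, "D")
})

test_that("threshold sweep exposes boundary sensitivity and stable calls", {
  pae <- synthetic_pae(300, list(c(30, 120), c(160, 280)), seed = 54)
  sw <- sweep_threshold(pae)
  expect_true(all(sw$per_threshold$class == "Mf"))
  expect_equal(unname(sw$class_fraction["Mf"]), 1)

  # an all-intermediate matrix flips class across the sweep
  M <- matrix(10.6, 120, 120)
  sep <- abs(outer(1:120, 1:120, "-"))
  M[sep < 5] <- 1
  sw2 <- sweep_threshold(load_pae(M))
  expect_gt(length(unique(sw2$per_threshold$class)), 1)
})

test_that("domain residue coverage is monotone in t_domain on planted blocks", {
  pae <- synthetic_pae(300, list(c(40, 130), c(170, 270)), seed = 55)
  sw <- sweep_threshold(pae)
  cov <- sw$per_threshold$domain_residues
  expect_true(all(diff(cov) >= 0))
})

test_that("partitions are deterministic, disjoint, sorted and exportable", {
  pae <- synthetic_pae(400, list(c(20, 100), c(130, 230), c(260, 380)),
                       seed = 56)
  p1 <- partition_pae(pae)
  p2 <- partition_pae(pae)
  expect_identical(p1$domains, p2$domains)
  starts <- vapply(p1$domains, `[`, numeric(1), 1)
  ends <- vapply(p1$domains, `[`, numeric(1), 2)
  expect_true(all(starts <= ends))
  expect_true(all(diff(starts) > 0))
  expect_true(all(ends[-length(ends)] < starts[-1]))
  expect_true(all(starts >= 1 & ends <= 400))

  bf <- withr::local_tempfile(fileext = ".bed")
  df <- write_partition_bed(p1, bf)
  expect_equal(df$start, starts - 1)   # 0-based half-open
  expect_equal(df$end, ends)
})
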