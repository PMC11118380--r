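test_that("kernel constants derive from the FWHM", {
  k <- make_kernel(fwhm = 5, span = 20)
  expect_equal(round(k$sigma, 2), 2.12)
  expect_equal(k$sigma, 5 / (2 * sqrt(2 * log(2))))
  expect_equal(k$weights[k$offsets == 0], 1)        # unit peak
  expect_equal(k$weights, rev(k$weights))           # symmetry
  expect_length(k$weights, 21L)
  expect_error(make_kernel(fwhm = 0), "positive")
  expect_error(make_kernel(span = 0), ">= 1")
})

test_that("smoothing matches the direct double-loop oracle", {
  set.seed(31)
  for (i in 1:20) {
    s <- random_protein(sample(50:300, 1), p_his = 0.05)
    expect_equal(delta_charge_profile(s), oracle_profile(s))
  }
})

test_that("isolated and paired histidines give the documented peaks", {
  k <- make_kernel()
  iso <- paste0(strrep("A", 40), "H", strrep("A", 40))
  prof <- delta_charge_profile(iso, k)
  expect_equal(max(prof), 1.0)                      # exactly 1
  expect_equal(which.max(prof), 41L)
  expect_length(find_peaks(prof), 0L)               # strict > 1
  pair <- paste0(strrep("A", 40), "HH", strrep("A", 40))
  prof2 <- delta_charge_profile(pair, k)
  sigma2 <- k$sigma^2
  expect_equal(max(prof2), 1 + exp(-1 / (2 * sigma2)))
  expect_equal(round(max(prof2), 2), 1.9)
  expect_true(all(delta_charge_profile(strrep("AGSTPQ", 20)) == 0))
})

test_that("profile maximum is bounded by the histidine count", {
  set.seed(17)
  for (i in 1:20) {
    s <- random_protein(sample(60:200, 1), p_his = 0.1)
    nh <- sum(strsplit(s, "")[[1]] == "H")
    expect_lte(max(delta_charge_profile(s)), nh + 1e-12)
  }
})

test_that("profile of the reversed sequence is the reversed profile", {
  set.seed(53)
  for (i in 1:15) {
    s <- random_protein(sample(40:150, 1), p_his = 0.08)
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(delta_charge_profile(rev_s),
                 rev(delta_charge_profile(s)))
  }
})

test_that("adding a histidine never decreases the profile", {
  set.seed(71)
  for (i in 1:15) {
    chars <- strsplit(random_protein(120, p_his = 0.05), "")[[1]]
    pos <- sample(which(chars != "H"), 1)
    before <- delta_charge_profile(paste(chars, collapse = ""))
    chars[pos] <- "H"
    after <- delta_charge_profile(paste(chars, collapse = ""))
    expect_true(all(after - before >= -1e-12))
  }
})

test_that("find_peaks matches the brute-force oracle on random proteins", {
  set.seed(5)
  for (i in 1:200) {
    s <- random_protein(sample(60:250, 1), p_his = 0.06)
    prof <- delta_charge_profile(s)
    pk <- find_peaks(prof)
    expect_identical(pk, oracle_peaks(prof))
    # necessary condition: a called peak needs >= 2 H in a 20-residue window
    for (p in pk) expect_gte(oracle_window_his(s, p), 2L)
  }
})

test_that("find_peaks handles plateaus, shoulders and merging", {
  # shoulder on a descending slope is not a peak
  expect_identical(find_peaks(c(5, 4, 3, 3, 2), min_peak_separation = 1),
                   1L)
  # plateau counts once at its first index
  expect_identical(find_peaks(c(0, 3, 3, 0), min_peak_separation = 1), 2L)
  # merge keeps the larger peak; ties go to the smaller index
  expect_identical(find_peaks(c(2, 0, 3, 0), min_peak_separation = 5), 3L)
  expect_identical(find_peaks(c(2, 0, 2, 0), min_peak_separation = 5), 1L)
  expect_identical(find_peaks(rep(0, 10)), integer(0))
  expect_identical(find_peaks(numeric(0)), integer(0))
})

test_that("regions extend 50 residues each side, clipped to the sequence", {
  expect_equal(extend_region(100, 50, 1000), c(50L, 150L))
  expect_equal(extend_region(10, 50, 1000), c(1L, 60L))
  expect_equal(extend_region(995, 50, 1000), c(945L, 1000L))
  expect_error(extend_region(0, 50, 100), "bounds")
})

test_that("disorder gating uses the either-side rule", {
  hi <- assess_disorder(rep(0.9, 100), c(10, 90), 50)
  expect_true(hi$disordered)
  lo <- assess_disorder(rep(0.1, 100), c(10, 90), 50)
  expect_false(lo$disordered)
  mixed <- c(rep(0.5, 49), 0, rep(0.1, 51))
  m <- assess_disorder(mixed, c(10, 90), 50)
  expect_true(m$disordered)          # N side 0.5 > 0.3 suffices
  expect_equal(m$disorder_n, mean(mixed[10:49]))
  expect_equal(m$disorder_c, mean(mixed[51:90]))
  # empty side scores 0
  edge <- assess_disorder(rep(0.9, 100), c(1, 50), 1)
  expect_equal(edge$disorder_n, 0)
})

test_that("PQ score reaches the kernel mass on a pure PQ flank", {
  k <- make_kernel()
  s <- paste0(strrep("PQ", 40), "A", strrep("G", 40))
  peak <- 81L
  sc <- pq_score(s, peak, c(31L, 121L), k)
  expect_equal(sc, sum(k$weights))   # interior of a pure P/Q stretch
  # P/Q-free region scores 0
  expect_equal(pq_score(strrep("AG", 60), 60L, c(10L, 110L), k), 0)
  # invariant under swapping P and Q
  swapped <- chartr("PQ", "QP", s)
  expect_equal(pq_score(swapped, peak, c(31L, 121L), k), sc)
})

test_that("protonation arithmetic follows Henderson-Hasselbalch", {
  expect_equal(his_protonation_fraction(6.0), 0.5)
  expect_equal(his_protonation_delta(7.4, 6.5), 0.202, tolerance = 1e-2)
  expect_equal(his_protonation_delta(7.0, 7.0), 0)
})

test_that("net charge, histidine runs and H-to-A mutation behave", {
  expect_equal(net_charge("KDE"), -1)
  expect_equal(net_charge("GGGG"), 0)
  expect_equal(net_charge("HHH", mode = "acidic", pH = 6.5),
               3 * his_protonation_fraction(6.5), tolerance = 1e-12)
  expect_equal(round(net_charge("HHH", mode = "acidic", pH = 6.5), 2), 0.72)
  expect_equal(longest_his_run("AHHHA"), 3L)
  expect_equal(longest_his_run("AGSA"), 0L)
  mut <- mutate_his_to_ala("HAH", c(1, 3))
  expect_equal(mut$sequence, "AAA")
  expect_equal(mut$n_replaced, 2L)
  nomut <- mutate_his_to_ala("AGSA", c(1, 4))
  expect_equal(nomut$sequence, "AGSA")
  expect_equal(nomut$n_replaced, 0L)
  # idempotence: no histidines remain in the mutated interval
  b <- synthetic_brd4()
  m <- mutate_his_to_ala(b$sequence, c(700, 1400))
  expect_equal(mutate_his_to_ala(m$sequence, c(700, 1400))$n_replaced, 0L)
  expect_equal(nchar(m$sequence), nchar(b$sequence))
})

test_that("composition enrichment is zero on itself and flags histidine", {
  s <- strrep("ACDEFGHIKLMNPQRSTVWY", 5)
  expect_equal(unname(composition_enrichment(s, s)), rep(0, 20),
               tolerance = 1e-12)
  enr <- composition_enrichment(strrep("H", 50), s)
  expect_equal(unname(which.max(enr)), which(names(enr) == "H"))
  expect_equal(enr[["H"]], log2((1 + 1e-4) / (0.05 + 1e-4)))
  # invariant to background order
  bg <- c("AAAA", "HHPQ", "GGGG")
  expect_equal(composition_enrichment("HPQ", bg),
               composition_enrichment("HPQ", rev(bg)))
  expect_error(composition_enrichment("", bg), "empty")
})

test_that("screen_proteome applies the disorder gate and sorts candidates", {
  specs <- list(list(class = "his_cluster_in_PQ"),
                list(class = "his_cluster_ordered"),
                list(class = "no_his"),
                list(class = "isolated_his"))
  sim <- simulate_proteome(4, motif_specs = specs, seed = 23)
  pre <- screen_proteome(sim$proteins, disorder = sim$disorder,
                         apply_disorder_gate = FALSE)
  post <- screen_proteome(sim$proteins, disorder = sim$disorder)
  ord_id <- sim$truth$protein_id[2]
  expect_true(ord_id %in% pre$accession)     # present before the gate
  expect_false(ord_id %in% post$accession)   # gated out (ordered context)
  pq_id <- sim$truth$protein_id[1]
  expect_true(pq_id %in% post$accession)
  hit <- post[post$accession == pq_id, ][1, ]
  expect_true(hit$peak_pos >= sim$truth$start[1] - 10 &&
              hit$peak_pos <= sim$truth$end[1] + 10)
  expect_false(sim$truth$protein_id[3] %in% pre$accession)  # H-free
  expect_true(all(diff(post$delta_charge) <= 1e-12))        # sorted
  funnel <- attr(post, "funnel")
  expect_equal(funnel$n_proteins, 4L)
  expect_gte(funnel$n_peaks, funnel$n_reported)
})

test_that("screen_proteome handles empty input and unknown disorder", {
  empty <- data.frame(accession = character(),
                      description = character(),
                      sequence = character(), stringsAsFactors = FALSE)
  res <- screen_proteome(empty)
  expect_equal(nrow(res), 0L)
  expect_true(all(c("accession", "delta_charge", "pq_score") %in%
                  names(res)))
  # no disorder information: candidates flagged unknown, excluded by gate
  one <- data.frame(accession = "P1", description = "",
                    sequence = paste0(strrep("A", 30), "HHHHHH",
                                      strrep("A", 30)),
                    stringsAsFactors = FALSE)
  gated <- screen_proteome(one)
  expect_equal(nrow(gated), 0L)
  ungated <- screen_proteome(one, apply_disorder_gate = FALSE)
  expect_equal(nrow(ungated), 1L)
  expect_true(is.na(ungated$disordered))
})

test_that("screen output is byte-deterministic", {
  sim <- simulate_proteome(6, motif_specs = rep(list(list(
    class = "his_cluster_in_PQ")), 6), seed = 77)
  a <- screen_proteome(sim$proteins, disorder = sim$disorder)
  b <- screen_proteome(sim$proteins, disorder = sim$disorder)
  fa <- tempfile(); fb <- tempfile()
  phdeconv:::write_results_tsv(a, fa)
  phdeconv:::write_results_tsv(b, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("expression join flags candidates above the cutoff", {
  specs <- list(list(class = "his_cluster_in_PQ"),
                list(class = "his_cluster_in_PQ"))
  sim <- simulate_proteome(2, motif_specs = specs, seed = 13)
  expr <- data.frame(gene_id = c(sim$truth$protein_id[1], "other"),
                     mean_count = c(100, 1))
  res <- screen_proteome(sim$proteins, disorder = sim$disorder,
                         expression = expr)
  expect_true(all(res$expressed[res$accession == sim$truth$protein_id[1]]))
  expect_false(any(res$expressed[res$accession == sim$truth$protein_id[2]]))
})
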