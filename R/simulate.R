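#' Simulate an expression matrix with planted regulatory-logic components
#'
#' Draws per-gene baselines, assigns each gene a planted regulatory-logic
#' label, converts the label into a component triple `(LPS, pH, INT)` in
#' log2-fold units, builds log2 condition means (the LPS component enters
#' both LPS conditions, pH enters both acidic conditions, INT only the
#' acidic LPS condition), adds independent Gaussian noise on the log2
#' scale (multiplicative on counts) and rounds to non-negative integer
#' counts.  Labels:
#' \itemize{
#'   \item `unassigned`: `(0, 0, 0)` (null genes);
#'   \item `pH_insensitive`: `(s e, 0, 0)`;
#'   \item `pH_only`: `(0, s e, 0)`;
#'   \item `pH_antagonistic`: `(s e, 0, -s e)`;
#'   \item `pH_synergistic`: `(s e, 0, s e)`;
#' }
#' with `e = effect_scale` and sign `s` drawn per gene (or fixed with
#' `signs = "positive"`).
#'
#' @param n_genes number of genes.
#' @param group_mix named probability vector over the labels above.
#' @param effect_scale planted component magnitude, log2 units.
#' @param noise_sd Gaussian noise standard deviation, log2 units.
#' @param n_replicate_sets complete 4-condition replicate sets.
#' @param baseline_range range of log2 baseline means (drawn uniformly).
#' @param signs `"random"` or `"positive"` sign of planted effects.
#' @param noise_model `"lognormal"` (default, matched to the log-linear
#'   analysis model) or `"nb"` (negative-binomial counts).
#' @param nb_dispersion NB dispersion (1/size) when `noise_model = "nb"`.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return list with `matrix` (an [expression_matrix()], counts on a
#'   common scale) and `truth` (data.frame `gene_id`, `beta_LPS`,
#'   `beta_pH`, `beta_INT`, `baseline`, `category`).
#' @export
simulate_expression <- function(n_genes = 5000,
                                group_mix = c(unassigned = 0.40,
                                              pH_insensitive = 0.20,
                                              pH_only = 0.10,
                                              pH_antagonistic = 0.20,
                                              pH_synergistic = 0.10),
                                effect_scale = 2, noise_sd = 0.25,
                                n_replicate_sets = 2,
                                baseline_range = c(3, 12),
                                signs = c("random", "positive"),
                                noise_model = c("lognormal", "nb"),
                                nb_dispersion = 0.1, seed = 1) {
  signs <- match.arg(signs); noise_model <- match.arg(noise_model)
  if (length(seed) != 1L || is.na(seed) || seed != round(seed))
    stop("seed must be a single integer")
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (effect_scale <= 0) stop("effect_scale must be > 0")
  if (!length(group_mix)) stop("group_mix must be non-empty")
  allowed <- c("unassigned", "pH_insensitive", "pH_only",
               "pH_antagonistic", "pH_synergistic")
  if (!all(names(group_mix) %in% allowed))
    stop("group_mix names must be among: ", paste(allowed, collapse = ", "))
  if (abs(sum(group_mix) - 1) > 1e-8) stop("group_mix must sum to 1")
  set.seed(as.integer(seed))

  gene_id <- sprintf("gene%05d", seq_len(n_genes))
  category <- sample(names(group_mix), n_genes, replace = TRUE,
                     prob = group_mix)
  s <- if (signs == "positive") rep(1, n_genes) else
    sample(c(-1, 1), n_genes, replace = TRUE)
  e <- effect_scale
  beta <- matrix(0, n_genes, 3, dimnames = list(NULL, c("LPS", "pH", "INT")))
  beta[category == "pH_insensitive", "LPS"] <- s[category == "pH_insensitive"] * e
  beta[category == "pH_only", "pH"] <- s[category == "pH_only"] * e
  ant <- category == "pH_antagonistic"
  beta[ant, "LPS"] <- s[ant] * e; beta[ant, "INT"] <- -s[ant] * e
  syn <- category == "pH_synergistic"
  beta[syn, "LPS"] <- s[syn] * e; beta[syn, "INT"] <- s[syn] * e
  baseline <- stats::runif(n_genes, baseline_range[1], baseline_range[2])

  # log2 condition means
  mu <- cbind(pH74     = baseline,
              pH74_LPS = baseline + beta[, "LPS"],
              pH65     = baseline + beta[, "pH"],
              pH65_LPS = baseline + beta[, "LPS"] + beta[, "pH"] +
                         beta[, "INT"])
  sets <- seq_len(n_replicate_sets)
  sample_id <- as.vector(t(outer(sets, PH_CONDITIONS,
                                 function(r, cc) paste0(cc, "_r", r))))
  design <- data.frame(sample_id = sample_id,
                       condition = rep(PH_CONDITIONS, n_replicate_sets),
                       replicate_set = rep(sets, each = 4L),
                       stringsAsFactors = FALSE)
  counts <- matrix(0, n_genes, nrow(design),
                   dimnames = list(gene_id, design$sample_id))
  for (j in seq_len(nrow(design))) {
    m <- mu[, design$condition[j]]
    counts[, j] <- if (noise_model == "lognormal")
      pmax(0, round(2^(m + stats::rnorm(n_genes, 0, noise_sd))))
    else
      stats::rnbinom(n_genes, mu = 2^m, size = 1 / nb_dispersion)
  }
  truth <- data.frame(gene_id = gene_id,
                      beta_LPS = beta[, "LPS"], beta_pH = beta[, "pH"],
                      beta_INT = beta[, "INT"], baseline = baseline,
                      category = category, stringsAsFactors = FALSE)
  list(matrix = expression_matrix(counts, design, normalized = FALSE),
       truth = truth)
}

#' Typical vertebrate amino-acid background frequencies
#'
#' @return named probability vector over the 20 standard amino acids,
#'   summing to 1; the default background of [simulate_proteome()].
#' @export
aa_background <- function() {
  f <- c(A = 7.0, C = 2.3, D = 4.9, E = 7.1, F = 3.6, G = 6.6, H = 2.6,
         I = 4.3, K = 5.7, L = 10.0, M = 2.2, N = 3.6, P = 6.1, Q = 4.8,
         R = 5.6, S = 8.4, T = 5.4, V = 6.0, W = 1.2, Y = 2.7)
  f / sum(f)
}

.sample_seq <- function(n, freqs) {
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

#' Simulate a proteome with planted histidine-cluster motifs
#'
#' Draws each protein from a background amino-acid distribution and
#' overwrites planted motifs at recorded positions.  Motif classes:
#' \itemize{
#'   \item `his_cluster_in_PQ`: a run of consecutive histidines followed
#'     by a proline/glutamine-rich block, with high sidecar disorder
#'     scores across the block and its flanks (the positive class);
#'   \item `his_cluster_ordered`: the same histidine cluster but with low
#'     disorder scores everywhere (rejected by the disorder gate);
#'   \item `isolated_his`: exactly one histidine in the whole protein;
#'   \item `no_his`: a histidine-free protein;
#'   \item `background`: pure background draw.
#' }
#' Sidecar scores are 0.82 inside disordered intervals and 0.12
#' elsewhere, with a small deterministic ripple.
#'
#' @param n_proteins number of proteins.
#' @param length_range integer range of protein lengths.
#' @param background_freqs named per-amino-acid probabilities (sum 1).
#' @param motif_specs list of per-protein specs, each a list with element
#'   `class` (above) and optional `h_run` (default 6) and `pq_block`
#'   (default 40); proteins beyond `length(motif_specs)` are background.
#' @param disorder_margin residues of high disorder added around a
#'   disordered motif block.
#' @param seed integer seed.
#' @return list with `proteins` (data.frame `accession`, `description`,
#'   `sequence`), `truth` (data.frame `protein_id`, `class`, `start`,
#'   `end`) and `disorder` (sidecar data.frame `protein_id`, `position`,
#'   `score`).
#' @export
simulate_proteome <- function(n_proteins, length_range = c(200, 400),
                              background_freqs = aa_background(),
                              motif_specs = NULL, disorder_margin = 60,
                              seed = 1) {
  if (length(seed) != 1L || is.na(seed) || seed != round(seed))
    stop("seed must be a single integer")
  if (!setequal(names(background_freqs), AA_STANDARD))
    stop("background_freqs must cover the 20 standard amino acids")
  if (abs(sum(background_freqs) - 1) > 1e-8)
    stop("background_freqs must sum to 1")
  set.seed(as.integer(seed))
  no_h <- background_freqs[setdiff(AA_STANDARD, "H")]
  no_h <- no_h / sum(no_h)

  proteins <- vector("list", n_proteins)
  truth <- list(); sidecar <- list()
  for (i in seq_len(n_proteins)) {
    acc <- sprintf("SYNP%04d", i)
    spec <- if (!is.null(motif_specs) && i <= length(motif_specs))
      motif_specs[[i]] else list(class = "background")
    cls <- spec$class
    h_run <- if (is.null(spec$h_run)) 6L else as.integer(spec$h_run)
    pq_block <- if (is.null(spec$pq_block)) 40L else as.integer(spec$pq_block)
    len <- sample(length_range[1]:length_range[2], 1L)
    motif_len <- switch(cls,
      his_cluster_in_PQ = h_run + pq_block,
      his_cluster_ordered = h_run,
      isolated_his = 1L, 0L)
    if (motif_len > len)
      stop("motif longer than protein for ", acc)
    chars <- .sample_seq(len,
      if (cls %in% c("no_his", "isolated_his")) no_h else background_freqs)
    start <- end <- NA_integer_
    dis_interval <- NULL
    if (cls %in% c("his_cluster_in_PQ", "his_cluster_ordered")) {
      start <- sample(seq(max(1L, disorder_margin),
                          len - motif_len - disorder_margin + 1L), 1L)
      end <- start + motif_len - 1L
      chars[start:(start + h_run - 1L)] <- "H"
      if (cls == "his_cluster_in_PQ") {
        # 90% P/Q block directly downstream of the run
        block <- rep(c("P", "Q"), length.out = pq_block)
        block[seq(10, pq_block, by = 10)] <- "G"
        chars[(start + h_run):(start + motif_len - 1L)] <- block
        dis_interval <- c(max(1L, start - disorder_margin),
                          min(len, end + disorder_margin))
      }
    } else if (cls == "isolated_his") {
      start <- end <- sample(seq(11L, len - 10L), 1L)
      chars[start] <- "H"
    }
    seqc <- paste(chars, collapse = "")
    proteins[[i]] <- data.frame(
      accession = acc,
      description = paste0("synthetic ", cls, " protein"),
      sequence = seqc, stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(protein_id = acc, class = cls,
                             start = start, end = end,
                             stringsAsFactors = FALSE)
    score <- 0.12 + 0.02 * sin(seq_len(len) / 23)
    if (!is.null(dis_interval))
      score[dis_interval[1]:dis_interval[2]] <-
        0.82 + 0.05 * sin(dis_interval[1]:dis_interval[2] / 31)
    sidecar[[i]] <- data.frame(protein_id = acc, position = seq_len(len),
                               score = round(pmin(1, pmax(0, score)), 3),
                               stringsAsFactors = FALSE)
  }
  list(proteins = do.call(rbind, proteins),
       truth = do.call(rbind, truth),
       disorder = do.call(rbind, sidecar))
}

#' Deterministic synthetic BRD4-like protein
#'
#' A 1400-residue stand-in (NOT the real BRD4 sequence; built entirely in
#' code) reproducing the sequence features relevant to the screen: an
#' ordered histidine-free N-terminal half (residues 1-700), a disordered
#' C-terminal region (701-1400) containing exactly 33 histidines, a
#' 6-histidine run at residues 721-726 adjacent to a 90% proline/glutamine
#' 40-residue block (741-780), and a second histidine/proline/glutamine
#' region at 1001-1080 with 9 histidines and 39 prolines or glutamines.
#' The remaining 18 histidines are scattered at least 25 residues apart so
#' they stay below the Delta-charge peak threshold.  A matching disorder
#' score vector (low N-terminal, high C-terminal) is returned alongside.
#'
#' @return list with `accession`, `description`, `sequence`, `idr`
#'   (`c(700, 1400)`) and `disorder` (length-1400 score vector).
#' @export
synthetic_brd4 <- function() {
  nterm_pat <- strsplit("MSTEGAKLVDRINELAGQFVDKSTRPELAMT", "")[[1]]
  chars <- rep(nterm_pat, length.out = 1400)
  # disordered C-terminal filler: uncharged, histidine-free
  chars[701:1400] <- rep(strsplit("PQSTGA", "")[[1]], length.out = 700)
  chars[721:726] <- "H"
  block <- rep(c("P", "Q"), length.out = 40)
  block[c(10, 20, 30, 40)] <- c("G", "S", "A", "T")
  chars[741:780] <- block
  scatter <- c(seq(810, 960, by = 30), seq(1100, 1375, by = 25))
  chars[scatter] <- "H"
  hpos2 <- c(1001, 1006, 1013, 1022, 1031, 1040, 1049, 1058, 1067)
  rest2 <- setdiff(1001:1080, hpos2)
  chars[hpos2] <- "H"
  chars[rest2[1:39]] <- rep(c("P", "Q"), length.out = 39)
  chars[rest2[40:71]] <- rep(c("G", "S", "A", "T"), length.out = 32)
  disorder <- c(0.12 + 0.02 * sin(seq_len(700) / 23),
                0.82 + 0.05 * sin(701:1400 / 31))
  list(accession = "SYNBRD4",
       description = "synthetic BRD4-like protein (constructed stand-in)",
       sequence = paste(chars, collapse = ""),
       idr = c(700L, 1400L),
       disorder = round(pmin(1, pmax(0, disorder)), 3))
}

#' Packaged toy fixtures
#'
#' Loads the small versioned fixtures shipped under `inst/extdata`: a
#' 12-gene expression table with its design sheet and a 5-protein FASTA
#' (including the [synthetic_brd4()] stand-in, an ordered histidine
#' cluster and a histidine-free protein) with its disorder sidecar.
#'
#' @return list with `expression` (an [expression_matrix()]), `proteins`
#'   (data.frame), `disorder` (sidecar data.frame).
#' @export
fixture_tables <- function() {
  pkg <- system.file("extdata", package = "phdeconv")
  em <- read_expression(file.path(pkg, "toy_expression.tsv"),
                        file.path(pkg, "toy_design.tsv"))
  proteins <- read_fasta(file.path(pkg, "toy_proteome.fasta"))
  disorder <- read_disorder(file.path(pkg, "toy_disorder.tsv"))
  list(expression = em, proteins = proteins, disorder = disorder)
}
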