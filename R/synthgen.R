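#' Parameters of a synthetic SRM experiment
#'
#' Describes the study design the generator emulates: a small targeted
#' panel measured across replicates, optionally with a light/heavy isotope
#' pair per peptide. Defaults describe a typical small SRM panel: three
#' transitions per peptide, three replicates, a two-fold light/heavy
#' ratio, and 20% multiplicative (log-normal) area noise.
#'
#' @param n_proteins Number of target proteins (>= 1).
#' @param peptides_per_protein Peptides per protein (>= 1).
#' @param transitions_per_peptide Transitions monitored per peptide (>= 1).
#' @param n_replicates Number of replicate runs (>= 1).
#' @param labeled Generate a light/heavy pair per transition?
#' @param true_ratio True light/heavy abundance ratio (> 0; labeled only).
#' @param base_area Expected XIC area of one heavy (or unlabeled)
#'   transition, in arbitrary area units.
#' @param noise_sigma Standard deviation of the log-normal multiplicative
#'   noise applied per transition measurement (0 = noise-free).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_proteins = 2, peptides_per_protein = 2,
                       transitions_per_peptide = 3, n_replicates = 3,
                       labeled = TRUE, true_ratio = 2, base_area = 1e5,
                       noise_sigma = 0.2, seed = 1) {
  counts <- c(n_proteins, peptides_per_protein, transitions_per_peptide,
              n_replicates)
  if (any(counts < 1)) stop("synth_spec: all counts must be >= 1", call. = FALSE)
  if (noise_sigma < 0) stop("synth_spec: noise_sigma must be >= 0", call. = FALSE)
  if (true_ratio <= 0) stop("synth_spec: true_ratio must be > 0", call. = FALSE)
  structure(list(n_proteins = as.integer(n_proteins),
                 peptides_per_protein = as.integer(peptides_per_protein),
                 transitions_per_peptide = as.integer(transitions_per_peptide),
                 n_replicates = as.integer(n_replicates),
                 labeled = isTRUE(labeled), true_ratio = true_ratio,
                 base_area = base_area, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Generate a synthetic SRM experiment with known ground truth
#'
#' Produces a Skyline-style report CSV plus the expected aggregated values
#' computed by direct summation inside the generator (independently of the
#' aggregation code it is used to test). Peptide sequences are random but
#' alphabet-valid and unique; precursor and product m/z are drawn in
#' [300, 1500] Th; the retention time of a peptide is drawn once and shared
#' by all its transitions and replicates; each transition measurement has
#' area `base_area * label_factor * exp(N(0, sigma^2))` with
#' `label_factor = true_ratio` for the light channel of a labeled design
#' and 1 otherwise. R's default Mersenne-Twister generator is used, so the
#' same spec and seed always yield byte-identical CSV text.
#'
#' @param spec A [synth_spec()].
#' @return A list with elements `report_csv` (a single CSV string),
#'   `truth` (per peptide: sequence, charge, per-assay expected SUM of
#'   areas named `"<replicate>:<label>"`, and for labeled designs the
#'   per-replicate light/heavy ratio of those sums), and `spec`.
#' @export
#' @examples
#' exp <- generate_srm_experiment(synth_spec(noise_sigma = 0, seed = 42))
#' exp$truth[[1]]$ratios  # exactly the true ratio everywhere
generate_srm_experiment <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  labels <- if (spec$labeled) c("light", "heavy") else "light"
  reps <- paste0("rep", seq_len(spec$n_replicates))

  n_pep <- spec$n_proteins * spec$peptides_per_protein
  seqs <- character(0)
  while (length(seqs) < n_pep) {
    s <- paste(sample(.aa_alphabet, sample(8:15, 1), replace = TRUE),
               collapse = "")
    if (!s %in% seqs) seqs <- c(seqs, s)
  }

  rows <- list()
  truth <- list()
  k <- 0L
  for (ip in seq_len(spec$n_proteins)) {
    for (jp in seq_len(spec$peptides_per_protein)) {
      k <- k + 1L
      pep_seq <- seqs[k]
      charge <- sample(2:3, 1)
      prec_mz <- canon_num(runif(1, 300, 1500))
      rt <- canon_num(runif(1, 5, 60))
      prod_mz <- canon_num(runif(spec$transitions_per_peptide, 300, 1500))
      frag <- paste0("y", seq(3, length.out = spec$transitions_per_peptide))
      sums <- numeric()
      for (r in reps) {
        for (lb in labels) {
          factor <- if (spec$labeled && lb == "light") spec$true_ratio else 1
          tot <- 0
          for (t in seq_len(spec$transitions_per_peptide)) {
            noise <- if (spec$noise_sigma > 0)
              exp(stats::rnorm(1, 0, spec$noise_sigma)) else 1
            area <- canon_num(spec$base_area * factor * noise)
            fwhm <- canon_num(runif(1, 0.05, 0.3))
            rows[[length(rows) + 1L]] <- data.frame(
              ProteinName = paste0("PROT_", ip),
              PeptideModifiedSequence = pep_seq,
              PrecursorMz = fmt_num(prec_mz),
              PrecursorCharge = charge,
              ProductMz = fmt_num(prod_mz[t]),
              ProductCharge = 1L,
              FragmentIon = frag[t],
              IsotopeLabelType = lb,
              ReplicateName = r,
              FileName = paste0(r, ".raw"),
              RetentionTime = fmt_num(rt),
              Area = fmt_num(area),
              Background = fmt_num(canon_num(area * 0.01)),
              Height = fmt_num(canon_num(area / fwhm)),
              Fwhm = fmt_num(fwhm),
              stringsAsFactors = FALSE)
            tot <- tot + area  # truth by direct summation
          }
          sums[[paste(r, lb, sep = ":")]] <- tot
        }
      }
      ratios <- NULL
      if (spec$labeled) {
        ratios <- vapply(reps, function(r) {
          h <- sums[[paste(r, "heavy", sep = ":")]]
          if (h == 0) NaN else sums[[paste(r, "light", sep = ":")]] / h
        }, numeric(1))
        names(ratios) <- reps
      }
      truth[[paste0(pep_seq, "/", charge)]] <-
        list(sequence = pep_seq, charge = charge, sums = sums, ratios = ratios)
    }
  }

  tab <- do.call(rbind, rows)
  con <- textConnection("csv_out", "w", local = TRUE)
  utils::write.table(tab, con, sep = ",", row.names = FALSE, quote = TRUE)
  close(con)
  list(report_csv = paste0(paste(csv_out, collapse = "\n"), "\n"),
       truth = truth, spec = spec)
}

#' Write a synthetic experiment to disk
#'
#' Emits the report CSV and a tab-separated truth sidecar with one row per
#' (peptide, assay) expected sum and one per (peptide, replicate) expected
#' ratio.
#'
#' @param exp Result of [generate_srm_experiment()].
#' @param csv_path Output path for the report CSV.
#' @param truth_path Optional output path for the truth TSV.
#' @return `csv_path`, invisibly.
#' @export
write_synth_experiment <- function(exp, csv_path, truth_path = NULL) {
  writeLines(sub("\n$", "", exp$report_csv), csv_path)
  if (!is.null(truth_path)) {
    rows <- list()
    for (key in names(exp$truth)) {
      tr <- exp$truth[[key]]
      for (a in names(tr$sums))
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = key, kind = "sum", which = a,
          value = fmt_num(tr$sums[[a]]), stringsAsFactors = FALSE)
      for (r in names(tr$ratios))
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = key, kind = "ratio", which = r,
          value = fmt_num(tr$ratios[[r]]), stringsAsFactors = FALSE)
    }
    utils::write.table(do.call(rbind, rows), truth_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(csv_path)
}
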