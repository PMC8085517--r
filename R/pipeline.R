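#' Run the full pseudoexon diagnosis pipeline on one observed transcript
#'
#' Stages: detect the insertion against the reference mRNA, localize it to
#' its intron of origin, resolve the placement with mutant splice
#' dinucleotides, infer the causal variant (when patient data is
#' available), score the created splice windows, and annotate the
#' DNA/RNA/protein consequences.
#'
#' @param model A [gene_model()].
#' @param observed Observed transcript sequence (already merged if it came
#'   as amplicons; see [merge_amplicons()]).
#' @param patient_intron_seq Optional transcript-oriented patient intron
#'   sequence.
#' @param variant Optional candidate causal [cdna_variant()] (e.g. from a
#'   VCF record).
#' @param models Optional named list of trained splice models (`wmm`,
#'   `mm1`, `maxent`) for the score panel.
#' @param external_scores Optional named numeric vector passed through to
#'   the panels (e.g. deep-network gain scores).
#' @param min_anchor Passed to [find_insertion()].
#' @return A list of class `pseudoexon_analysis`: `event`, `call`,
#'   `windows`, `panels` (donor/acceptor score panels), `consequence`,
#'   `report` (one-row tibble), `flags`. When the observed sequence equals
#'   the reference, a list with `no_insertion = TRUE`.
#' @export
analyze_case <- function(model, observed, patient_intron_seq = NULL,
                         variant = NULL, models = list(),
                         external_scores = NULL, min_anchor = 15L) {
  ref <- transcript_seq(model)
  event <- find_insertion(ref, toupper(observed), min_anchor = min_anchor)
  if (is.null(event)) {
    return(structure(list(no_insertion = TRUE,
                          report = tibble::tibble(
                            derivation = "no insertion detected")),
                     class = "pseudoexon_analysis"))
  }
  located <- locate_in_intron(model, event)
  flags <- character()
  if (!is.na(located$warning)) flags <- c(flags, located$warning)
  call <- resolve_candidates(model, located,
                             patient_intron_seq = patient_intron_seq,
                             variant = variant)
  if (!is.null(patient_intron_seq) && is.null(variant)) {
    call <- infer_causal_variant(model, call, patient_intron_seq)
  } else if (!is.null(variant)) {
    call$side <- classify_variant_side(model, call, variant)
  }
  call$hgvs_rna <- format_rna_insertion(model, call)
  if (!is.null(call$causal_variant)) {
    call$hgvs_dna <- format_cdna_variant(call$causal_variant)
  }
  cons <- consequence_report(model, call)
  call$hgvs_protein <- cons$protein_hgvs
  mut_intron <- if (!is.null(patient_intron_seq)) patient_intron_seq else {
    mm <- model
    mm$genome_seq <- apply_variant_to_genome(model, call$causal_variant)
    intron_seq_tx(mm, call$intron_index)
  }
  windows <- pseudoexon_windows(model, call, mut_intron)
  panels <- list(
    donor = score_panel(windows$donor$reference, windows$donor$mutant,
                        models = models,
                        external_scores = external_scores),
    acceptor = score_panel(windows$acceptor$reference,
                           windows$acceptor$mutant,
                           models = drop_length_mismatched(models, 23L))
  )
  report <- render_case_report(call, panels$donor, cons, flags)
  structure(list(event = event, call = call, windows = windows,
                 panels = panels, consequence = cons, report = report,
                 flags = flags),
            class = "pseudoexon_analysis")
}

# Keep only models applicable to windows of length L (exact maxent models
# trained at another length are dropped rather than mis-applied).
drop_length_mismatched <- function(models, L) {
  keep <- models
  if (!is.null(keep$wmm) && keep$wmm$L != L) keep$wmm <- NULL
  if (!is.null(keep$mm1) && keep$mm1$L != L) keep$mm1 <- NULL
  if (!is.null(keep$maxent) && inherits(keep$maxent, "maxent_model") &&
      keep$maxent$L != L) {
    keep$maxent <- NULL
  }
  keep
}

# Side classification when the variant came from a VCF rather than a
# patient intron comparison.
classify_variant_side <- function(model, call, variant) {
  g <- cdna_to_genomic(model, variant$coord)
  k <- call$intron_index
  b <- intron_bounds(model)
  row <- b[b$index == k, ]
  if (g < row$start || g >= row$end) return(NA_character_)
  local <- if (model$strand == "+") g - row$start + 1L else row$end - g
  loc <- span_local_bounds(model, k, call$span)
  s <- loc[["start"]]; e <- loc[["end"]]
  if (local %in% c(e + 1L, e + 2L)) "donor-created"
  else if (local %in% seq.int(e - 2L, e + 6L)) "donor-strengthened"
  else if (local %in% c(s - 2L, s - 1L)) "acceptor-created"
  else if (local %in% seq.int(s - 20L, s + 2L)) "acceptor-strengthened"
  else NA_character_
}

#' @export
print.pseudoexon_analysis <- function(x, ...) {
  if (isTRUE(x$no_insertion)) {
    cat("<pseudoexon_analysis> no insertion detected\n")
    return(invisible(x))
  }
  print(x$call)
  cat(sprintf("  RNA: %s\n  protein: %s\n", x$call$hgvs_rna,
              x$call$hgvs_protein %||% NA))
  invisible(x)
}

#' Run the pipeline on a synthetic case and compare with its truth
#'
#' @param case A `synthetic_case`.
#' @param route `"intron"` uses the patient intron sequence, `"variant"`
#'   supplies the planted variant directly (the VCF route).
#' @return A list with the `analysis` and a logical vector `checks` of
#'   field-by-field agreement with the planted truth.
#' @export
recover_case <- function(case, route = c("intron", "variant")) {
  route <- match.arg(route)
  truth <- case$truth
  an <- analyze_case(
    case$gene, truth$mutant_transcript,
    patient_intron_seq = if (route == "intron") mutant_intron_seq(case),
    variant = if (route == "variant") case$variant
  )
  cv <- an$call$causal_variant
  checks <- c(
    intron_index = an$call$intron_index == truth$intron_index,
    span_start = an$call$span$start == truth$span$start,
    span_end = an$call$span$end == truth$span$end,
    variant = !is.null(cv) &&
      format_cdna_variant(cv) == truth$hgvs_dna,
    side = identical(an$call$side, truth$side),
    hgvs_rna = an$call$hgvs_rna == truth$hgvs_rna,
    hgvs_protein = identical(an$call$hgvs_protein, truth$hgvs_protein),
    residue = identical(an$consequence$first_affected_residue,
                        truth$first_affected_residue),
    stops = identical(as.integer(an$consequence$stop_offsets),
                      as.integer(truth$stop_offsets)),
    classification = an$consequence$classification == truth$classification
  )
  list(analysis = an, checks = checks, ok = all(checks))
}

# --- flat key=value config + command wrappers -------------------------------

#' Read a flat key=value pipeline configuration file
#'
#' Lines of `key = value`; `#` comments and blank lines ignored. Values in
#' `overrides` (e.g. from command-line flags) win over the file.
#'
#' @param path Config file path (optional).
#' @param overrides Named list of overriding values.
#' @return Named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
    for (ln in readLines(path)) {
      ln <- sub("#.*$", "", ln)
      if (!grepl("=", ln, fixed = TRUE)) next
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      key <- trimws(kv[1L])
      val <- trimws(paste(kv[-1L], collapse = "="))
      if (nzchar(key)) cfg[[key]] <- utils::type.convert(val, as.is = TRUE)
    }
  }
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  structure(cfg, class = c("pipeline_config", "list"))
}

config_get <- function(config, key, default = NULL, required = FALSE) {
  val <- config[[key]] %||% default
  if (required && is.null(val)) {
    stop(sprintf("config key '%s' is required", key))
  }
  val
}

#' Simulate fixture cases from a configuration
#'
#' Config keys: `out_dir` (required), `seed` (default 1), `n_cases`
#' (default 1), `n_exons`, `strand` (`+`, `-` or `mixed`), `pe_len`,
#' `depth`, `mode` (or `mixed`), `intron_min`, `intron_max`,
#' `normal_fraction`.
#'
#' @param config A `pipeline_config` (or plain named list).
#' @return Tibble of case directories and truth summaries, invisibly.
#' @export
cmd_simulate <- function(config) {
  out_dir <- config_get(config, "out_dir", required = TRUE)
  seed <- config_get(config, "seed", 1L)
  n_cases <- config_get(config, "n_cases", 1L)
  intron_min <- config_get(config, "intron_min", 1000L)
  intron_max <- config_get(config, "intron_max", 8000L)
  if (intron_min < 200L || intron_max < intron_min) {
    stop("usage error: intron length bounds must satisfy 200 <= intron_min <= intron_max")
  }
  modes <- c("donor-created", "acceptor-created", "donor-strengthened",
             "acceptor-strengthened")
  rows <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    s <- child_seed(seed, i)
    strand <- config_get(config, "strand", "mixed")
    if (strand == "mixed") strand <- if (i %% 2L == 0L) "-" else "+"
    mode <- config_get(config, "mode", "mixed")
    if (mode == "mixed") mode <- modes[1L + (i %% 4L)]
    gene <- make_toy_gene(s, n_exons = config_get(config, "n_exons", 3L),
                          intron_len_range = c(intron_min, intron_max),
                          strand = strand,
                          gene_id = sprintf("TOY%03d", i))
    k <- 1L + (i %% (n_exons(gene) - 1L))
    iw <- intron_width(gene, k)
    pe_len <- config_get(config, "pe_len", 50L + (i * 7L) %% 70L)
    depth <- config_get(config, "depth",
                        min(250L + (i * 131L) %% 2000L,
                            iw - pe_len - 210L))
    sc <- plant_pseudoexon_cassette(gene, k, pe_len, depth, mode,
                                    seed = s)
    dir_i <- file.path(out_dir, sprintf("case%03d", i))
    write_fixtures(sc, dir_i,
                   include_normal_fraction =
                     config_get(config, "normal_fraction", 0))
    rows[[i]] <- tibble::tibble(case = basename(dir_i), dir = dir_i,
                                gene_id = gene$gene_id, strand = strand,
                                mode = mode, intron = k,
                                pe_len = sc$truth$pe_len,
                                dna = sc$truth$hgvs_dna)
  }
  invisible(do.call(rbind, rows))
}

#' Analyze a fixture directory (or explicit file set) from a configuration
#'
#' Config keys: `genome`, `gff3`, `transcripts`, `gene_id`, and optionally
#' `patient_intron` (FASTA) or `vcf`; `out_dir` for the JSON/TSV report;
#' `min_anchor`.
#'
#' @param config A `pipeline_config`.
#' @return The `pseudoexon_analysis` (or no-insertion record), invisibly;
#'   writes `report.json` and `report.tsv` when `out_dir` is set.
#' @export
cmd_analyze <- function(config) {
  model <- load_gene_model(config_get(config, "gff3", required = TRUE),
                           config_get(config, "genome", required = TRUE),
                           config_get(config, "gene_id", "TOY1"))
  txs <- Biostrings::readDNAStringSet(
    config_get(config, "transcripts", required = TRUE))
  patient_intron <- NULL
  if (!is.null(config[["patient_intron"]])) {
    patient_intron <- as.character(Biostrings::readDNAStringSet(
      config[["patient_intron"]]))[[1L]]
  }
  variant <- NULL
  if (is.null(patient_intron) && !is.null(config[["vcf"]])) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF input requires the vcfR package")
    }
    v <- vcfR::read.vcfR(config[["vcf"]], verbose = FALSE)
    fix <- vcfR::getFIX(v)
    fix <- if (is.matrix(fix)) fix[1L, ] else fix
    g <- as.integer(fix[["POS"]]) - 1L
    ref <- fix[["REF"]]; alt <- fix[["ALT"]]
    if (model$strand == "-") { ref <- revcomp(ref); alt <- revcomp(alt) }
    variant <- cdna_variant(genomic_to_cdna(model, g), ref, alt)
  }
  # analyze the pseudoexon-bearing isoform: the first transcript that
  # differs from the reference, otherwise report no insertion
  ref <- transcript_seq(model)
  obs <- as.character(txs)
  pick <- which(obs != ref)
  observed <- if (length(pick) == 0L) obs[[1L]] else obs[[pick[1L]]]
  an <- analyze_case(model, observed, patient_intron_seq = patient_intron,
                     variant = variant,
                     min_anchor = config_get(config, "min_anchor", 15L))
  out_dir <- config[["out_dir"]]
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_case_report(an$report, file.path(out_dir, "report.json"))
    utils::write.table(an$report, file.path(out_dir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(an)
}

#' Score splice windows listed in a text/FASTA file
#'
#' Each input window is scored with the consensus value and any trained
#' models in `models`; input case is ignored. Window kind is inferred from
#' length (9 = donor, 23 = acceptor).
#'
#' @param config A `pipeline_config` with optional `out_dir`.
#' @param windows Character vector of window sequences, or a path to a
#'   FASTA/plain-text file (one window per record/line).
#' @param models Optional named list of trained models.
#' @return A tibble with one row per window and metric.
#' @export
cmd_score <- function(config, windows, models = list()) {
  if (length(windows) == 1L && file.exists(windows)) {
    first <- readLines(windows, n = 1L)
    windows <- if (length(first) && startsWith(first, ">")) {
      as.character(Biostrings::readDNAStringSet(windows))
    } else {
      x <- trimws(readLines(windows))
      x[nzchar(x)]
    }
  }
  windows <- toupper(as.character(windows))
  if (length(windows) == 0L) {
    return(tibble::tibble(window = character(), kind = character(),
                          metric = character(), score = numeric()))
  }
  rows <- lapply(windows, function(w) {
    kind <- if (nchar(w) == 9L) "donor" else if (nchar(w) == 23L) "acceptor"
            else stop(sprintf("window '%s' is neither 9 nt nor 23 nt", w))
    sw <- splice_window(kind, w)
    p <- score_panel(sw, NULL, models = drop_length_mismatched(models,
                                                               nchar(w)))
    tibble::tibble(window = w, kind = kind, metric = p$metric,
                   score = p$reference)
  })
  out <- do.call(rbind, rows)
  out_dir <- config[["out_dir"]]
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out, file.path(out_dir, "scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}
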