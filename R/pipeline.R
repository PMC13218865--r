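# Orchestration: configuration, the end-to-end run, publication-style
# reports, and the run manifest. A thin command-line wrapper around
# run_pipeline() ships in inst/exec/rvburden.

#' Build and validate a run configuration
#'
#' @param vcf,annotation,panel,gene_list Input paths (VCF, annotation TSV,
#'   panel TSV, one-symbol-per-line gene list).
#' @param out_dir Output directory.
#' @param thresholds A [qc_thresholds()].
#' @param criteria A [prioritisation_criteria()].
#' @param default_an Named fallback allele numbers per population.
#' @param populations,primary Panels tested and the panel driving the
#'   significance flag.
#' @param window_size,step,quantile Constraint-profile parameters.
#' @param site_threshold,min_variation Splice-event call parameters.
#' @param seed Integer seed for any stochastic step.
#' @return An `rv_run_config` list.
#' @export
run_config <- function(vcf, annotation, panel, gene_list, out_dir,
                       thresholds = qc_thresholds(),
                       criteria = prioritisation_criteria(),
                       default_an = c(NFE = 68058, Global = 152312,
                                      CSVS = 4074),
                       populations = c("NFE", "Global", "CSVS"),
                       primary = "NFE",
                       window_size = 90, step = 30, quantile = 0.25,
                       site_threshold = 60, min_variation = 10,
                       seed = 1L) {
  paths <- c(vcf = vcf, annotation = annotation, panel = panel,
             gene_list = gene_list)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    stop("config_error: missing input file(s): ",
         paste(names(missing), "=", missing, collapse = ", "))
  stopifnot(inherits(thresholds, "qc_thresholds"),
            inherits(criteria, "prioritisation_criteria"),
            primary %in% populations, window_size >= 1, step >= 1,
            quantile >= 0, quantile <= 1)
  structure(list(paths = as.list(paths), out_dir = out_dir,
                 thresholds = thresholds, criteria = criteria,
                 default_an = default_an, populations = populations,
                 primary = primary, window_size = window_size, step = step,
                 quantile = quantile, site_threshold = site_threshold,
                 min_variation = min_variation, seed = as.integer(seed)),
            class = "rv_run_config")
}

# stable md5 of the canonicalised config (used to stamp every output)
config_hash <- function(config) {
  cfg <- rapply(unclass(config), unclass, how = "replace")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, digits = NA, auto_unbox = TRUE, force = TRUE)
  unname(tools::md5sum(tmp))
}

.write_stamped_tsv <- function(x, path, hash) {
  readr::write_lines(paste0("# config_hash: ", hash), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the burden pipeline end to end
#'
#' Steps: read + QC the cohort VCF, restrict to the gene family, apply the
#' rarity filter, burden-scan all panels (functional and synonymous tracks),
#' report multi-carriers and synonymous/missense sharing, and write
#' publication-style TSVs plus a machine-readable audit-count log and a run
#' manifest (package version, config hash, input checksums). Every output
#' file starts with a `# config_hash:` stamp, so any threshold change
#' changes every artifact.
#'
#' @param config An [run_config()] object.
#' @param steps Subset of
#'   `c("qc", "burden", "cooccur", "report")` or `"all"`.
#' @return Invisibly, a list with the intermediate objects and output paths.
#' @export
run_pipeline <- function(config, steps = "all") {
  stopifnot(inherits(config, "rv_run_config"))
  all_steps <- c("qc", "burden", "cooccur", "report")
  if (identical(steps, "all")) steps <- all_steps
  stopifnot(all(steps %in% all_steps))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  set.seed(config$seed)
  out <- list(config = config, hash = hash, paths = character(0))

  gene_list <- read_gene_list(config$paths$gene_list)
  panel <- read_panel(config$paths$panel)

  calls <- read_cohort_vcf(config$paths$vcf, config$paths$annotation,
                           config$thresholds)
  audit_counts <- list(
    n_individuals = calls$n_individuals,
    n_variants_raw = nrow(calls$variants),
    n_genotypes_failed = nrow(calls$audit),
    qc_fail_reasons = as.list(table(calls$audit$reason))
  )
  calls <- restrict_to_genes(calls, gene_list)
  audit_counts$n_variants_on_target <- nrow(calls$variants)
  calls <- rarity_filter(calls, panel, config$criteria,
                         populations = config$populations)
  audit_counts$n_variants_rare <- nrow(calls$variants)
  audit_counts$n_by_class <- as.list(table(calls$variants$class))
  out$calls <- calls
  out$audit_counts <- audit_counts

  if ("burden" %in% steps || "report" %in% steps) {
    out$burden <- burden_scan(calls, panel, gene_list,
                              populations = config$populations,
                              primary = config$primary,
                              criteria = config$criteria,
                              default_an = config$default_an)
  }
  if ("cooccur" %in% steps || "report" %in% steps) {
    out$carriers <- find_multicarriers(calls, gene_list)
    out$sharing <- syn_mis_sharing(calls, gene_list)
  }

  if ("report" %in% steps) {
    p <- function(f) file.path(config$out_dir, f)
    .write_stamped_tsv(tidy(out$burden), p("burden_scan.tsv"), hash)
    write_burden_report(out$burden, p("burden_report.tsv"), hash = hash)
    carriers_flat <- if (nrow(out$carriers) > 0) {
      tidyr::unnest(out$carriers, c("variant_ids", "classes", "genotypes"))
    } else {
      tibble::tibble(indiv = character(), gene = character())
    }
    .write_stamped_tsv(carriers_flat, p("carriers.tsv"), hash)
    .write_stamped_tsv(out$sharing, p("syn_mis_sharing.tsv"), hash)
    .write_stamped_tsv(calls$audit, p("qc_audit.tsv"), hash)
    jsonlite::write_json(audit_counts, p("audit_counts.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- list(
      tool = "rvburden",
      version = as.character(packageVersion("rvburden")),
      config_hash = hash,
      seed = config$seed,
      inputs = lapply(config$paths, function(f)
        list(path = f, md5 = unname(tools::md5sum(f))))
    )
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
    out$paths <- vapply(c("burden_scan.tsv", "burden_report.tsv",
                          "carriers.tsv", "syn_mis_sharing.tsv",
                          "qc_audit.tsv", "audit_counts.json",
                          "manifest.json"), p, character(1))
  }
  invisible(out)
}

#' Reconstruct odds ratios from published summary statistics
#'
#' Given aggregate case alt-allele counts and the control MAF as printed in a
#' published gene-burden table, recomputes the sample odds ratio
#' `(a / (A - a)) / (maf / (1 - maf))`. Deviations from the printed values
#' reflect only the rounding of the printed MAF.
#'
#' @param tab Tibble (or TSV path) with columns `case_ac`, `case_an`,
#'   `control_maf`; extra columns pass through. Defaults to the packaged
#'   published summary table.
#' @return The table with a `reconstructed_or` column.
#' @export
reconstruct_published_or <- function(tab = NULL) {
  if (is.null(tab))
    tab <- system.file("extdata", "published_burden.tsv",
                       package = "rvburden", mustWork = TRUE)
  if (is.character(tab))
    tab <- readr::read_tsv(tab, show_col_types = FALSE, comment = "#")
  stopifnot(all(c("case_ac", "case_an", "control_maf") %in% names(tab)))
  a <- tab$case_ac
  c_ <- tab$case_an - tab$case_ac
  tab$reconstructed_or <- ifelse(
    tab$control_maf == 0,
    ifelse(a > 0, Inf, NaN),
    (a / c_) / (tab$control_maf / (1 - tab$control_maf)))
  tab
}

#' Demo run on a packaged synthetic dataset
#'
#' Simulates a small cohort with planted enrichment, writes its artifacts,
#' and runs the full pipeline over them.
#'
#' @param dir Working directory for inputs and outputs.
#' @param seed Seed.
#' @return The [run_pipeline()] result, invisibly.
#' @export
demo_pipeline <- function(dir = tempfile("rvburden_demo"), seed = 1L) {
  spec_all <- default_gene_spec()
  keep <- unique(c("TLR9", "TNFRSF1B", "FAS", head(spec_all$gene, 17)))
  genes <- spec_all[spec_all$gene %in% keep, ]
  cfg <- sim_config(
    n_cases = 100, genes = genes, maf_range = c(1e-5, 1e-3),
    enrichment = c(TLR9 = 10, TNFRSF1B = 10, FAS = 8),
    planted_pairs = c(TLR9 = 1, TNFRSF1B = 1),
    planted_syn_mis = c(FAS = 1),
    seed = seed)
  sim <- simulate_cohort(cfg)
  paths <- write_simulation(sim, file.path(dir, "inputs"))
  rc <- run_config(vcf = paths[["vcf"]], annotation = paths[["annotation"]],
                   panel = paths[["panel"]], gene_list = paths[["genes"]],
                   out_dir = file.path(dir, "outputs"), seed = seed)
  run_pipeline(rc)
}
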