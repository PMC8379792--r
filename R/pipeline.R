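#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. Cutoffs must be positive;
#' `pcit_node_policy` chooses the node universe of the trio filter — DE genes
#' plus RIF-significant TFs (default, keeps the O(n^3) loop small) or DE
#' genes plus every catalog TF present in the matrix.
#'
#' @param input path to the expression matrix file.
#' @param design path to the two-column sample/condition file.
#' @param tfs path to the TF catalog (one id per line).
#' @param reference reference condition label.
#' @param outdir output directory for artifacts.
#' @param format `"tsv"`, `"csv"` or `"mtx"`.
#' @param kind `"counts"` or `"normalized"`.
#' @param rownames_path,colnames_path sidecars for `format = "mtx"`.
#' @param de_cutoff differential-expression cutoff (default 1.96).
#' @param rif_cutoff RIF significance cutoff (default 1.96).
#' @param pcit_node_policy `"de_plus_sig_tfs"` or `"de_plus_all_tfs"`.
#' @param eq7_variant `"corrected"` or `"as_printed"` (see [pcit()]).
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters for the simulate subcommand).
#' @param quiet suppress stage messages.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, design, tfs, reference, outdir,
                            format = "tsv", kind = "counts",
                            rownames_path = NULL, colnames_path = NULL,
                            de_cutoff = 1.96, rif_cutoff = 1.96,
                            pcit_node_policy = c("de_plus_sig_tfs",
                                                 "de_plus_all_tfs"),
                            eq7_variant = c("corrected", "as_printed"),
                            seed = 1L, quiet = FALSE) {
  pcit_node_policy <- match.arg(pcit_node_policy)
  eq7_variant <- match.arg(eq7_variant)
  if (de_cutoff <= 0 || rif_cutoff <= 0) stop("cutoffs must be positive")
  structure(as.list(environment()), class = "pipeline_config")
}

# Run `expr` as pipeline stage `name`; any error is rethrown prefixed with
# the stage so a CLI failure names where it happened.
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' In-memory end-to-end analysis
#'
#' Runs the four pipeline stages on objects already in memory: data
#' adjustment (TPM + half-of-means filter + log2 for counts; filter only for
#' pre-normalized input), the standardized differential-expression contrast,
#' RIF scoring, and per-condition PCIT with network assembly.
#'
#' @param m an [expression_matrix()].
#' @param d a [condition_design()].
#' @param tfs character vector of TF ids.
#' @param de_cutoff,rif_cutoff positive cutoffs (defaults 1.96).
#' @param pcit_node_policy,eq7_variant see [pipeline_config()].
#' @param log a function taking a character message, or NULL.
#' @return list with components `normalized`, `filter_report`, `diff_table`,
#'   `de`, `rif_input`, `rif_table`, `significant_tfs`, `pcit`, `networks`,
#'   `hri`.
#' @export
analyze <- function(m, d, tfs, de_cutoff = 1.96, rif_cutoff = 1.96,
                    pcit_node_policy = c("de_plus_sig_tfs", "de_plus_all_tfs"),
                    eq7_variant = c("corrected", "as_printed"), log = NULL) {
  pcit_node_policy <- match.arg(pcit_node_policy)
  eq7_variant <- match.arg(eq7_variant)
  say <- if (is.null(log)) function(...) invisible() else log

  norm <- run_stage("adjustment", {
    if (m$kind == "counts") {
      f <- filter_genes(tpm_normalize(m))
      list(m = log_normalize(f$matrix), report = f$report)
    } else {
      f <- filter_genes(m)
      list(m = f$matrix, report = f$report)
    }
  })
  say(sprintf("[adjustment] %d/%d genes kept, %d samples",
              length(norm$report$kept), length(m$gene_ids),
              length(m$sample_ids)))

  dt <- run_stage("diffexp", reverter_diff(norm$m, d))
  de <- run_stage("diffexp", classify_de(dt, de_cutoff, tfs))
  say(sprintf("[diffexp] %d up, %d down at cutoff %.3g",
              sum(de$status == "up"), sum(de$status == "down"), de_cutoff))

  rin <- run_stage("rif", build_rif_input(norm$m, de, tfs, d))
  rift <- run_stage("rif", rif_scores(rin, rif_cutoff))
  sig <- run_stage("rif", significant_tfs(rift))
  say(sprintf("[rif] %d TFs scored against %d DE genes, %d significant",
              length(rin$tf_ids), length(rin$de_ids), length(sig)))

  node_tfs <- if (pcit_node_policy == "de_plus_sig_tfs") sig else rin$tf_ids
  nodes <- union(rin$de_ids, node_tfs)
  pc <- run_stage("pcit", {
    if (length(nodes) >= 2) {
      pcit_per_condition(norm$m, d, nodes, eq7_variant)
    } else {
      # fewer than two qualifying nodes: the network is trivially edgeless
      say(sprintf("[pcit] only %d node(s) qualify; emitting empty networks",
                  length(nodes)))
      trivial <- structure(list(
        significant = matrix(FALSE, length(nodes), length(nodes),
                             dimnames = list(nodes, nodes)),
        weights = diag(1, length(nodes), length(nodes)),
        node_ids = nodes, skipped_trios = 0, eq7_variant = eq7_variant),
        class = "pcit_result")
      stats::setNames(list(trivial, trivial), c(d$reference, d$alternate))
    }
  })
  nets <- run_stage("network",
                    build_networks(pc[[1]], pc[[2]], tfs,
                                   conditions = c(d$reference, d$alternate)))
  hri <- run_stage("network", hri_table(nets[[1]], nets[[2]], rift))
  say(sprintf("[pcit] %d nodes; %d edges (%s), %d edges (%s)",
              length(nodes), nrow(nets[[1]]$edges), d$reference,
              nrow(nets[[2]]$edges), d$alternate))

  list(normalized = norm$m, filter_report = norm$report, diff_table = dt,
       de = de, rif_input = rin, rif_table = rift, significant_tfs = sig,
       pcit = pc, networks = nets, hri = hri)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline from files to an artifact directory
#'
#' Reads the matrix, design and TF catalog named in the config, runs
#' [analyze()], and writes the artifacts in stage order: normalized matrix,
#' filter report, differential-expression tables, RIF table, significant-TF
#' list, per-condition edge lists (TSV and SIF), the high-regulatory-impact
#' TF table, a run log and a JSON manifest echoing the config, package
#' version, seed and row counts. Reruns with the same config are
#' byte-identical. Any stage error aborts with a message naming the stage.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the [analyze()] result list plus `outdir`.
#' @export
run_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(msg) {
    log_lines <<- c(log_lines, msg)
    if (!cfg$quiet) message(msg)
  }

  m <- run_stage("ingest", read_expression(cfg$input, cfg$format, cfg$kind,
                                           cfg$rownames_path,
                                           cfg$colnames_path))
  d <- run_stage("ingest", read_design(cfg$design, cfg$reference))
  tfs <- run_stage("ingest", read_tf_catalog(cfg$tfs))
  say(sprintf("[ingest] %d genes x %d samples (%s), %d TFs in catalog",
              length(m$gene_ids), length(m$sample_ids), m$kind, length(tfs)))

  res <- analyze(m, d, tfs, cfg$de_cutoff, cfg$rif_cutoff,
                 cfg$pcit_node_policy, cfg$eq7_variant, log = say)

  out <- function(f) file.path(cfg$outdir, f)
  write_expression(res$normalized, out("normalized_matrix.tsv"))
  write_filter_report(res$filter_report, out("filter_report.tsv"))
  write_tsv(res$diff_table, out("diff_table.tsv"))
  write_tsv(res$de, out("de_classification.tsv"))
  write_tsv(res$rif_table[c("TF", "avgexpr", "RIF1", "RIF2",
                            "rif1_raw", "rif2_raw", "sig1", "sig2")],
            out("rif_table.tsv"))
  writeLines(res$significant_tfs, out("significant_tfs.txt"))
  for (net in res$networks) {
    write_edges_tsv(net, out(sprintf("edges_%s.tsv", net$condition)))
    write_sif(net, out(sprintf("edges_%s.sif", net$condition)))
  }
  write_tsv(res$hri, out("hri_table.tsv"))
  writeLines(log_lines, out("run.log"))

  manifest <- list(
    package = "tfwire",
    version = as.character(utils::packageVersion("tfwire")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "quiet")],
    dimensions = list(
      genes_in = length(m$gene_ids),
      samples = length(m$sample_ids),
      genes_kept = length(res$filter_report$kept),
      de_genes = length(res$rif_input$de_ids),
      tfs_scored = length(res$rif_input$tf_ids),
      tfs_significant = length(res$significant_tfs),
      edges = stats::setNames(
        lapply(res$networks, function(n) nrow(n$edges)),
        vapply(res$networks, `[[`, "", "condition"))
    )
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  say(sprintf("[done] artifacts in %s", cfg$outdir))
  invisible(c(res, list(outdir = cfg$outdir)))
}
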