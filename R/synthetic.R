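#' Specification for the synthetic two-condition generator
#'
#' Describes a simulated experiment with known ground truth: a block of
#' module genes and one planted TF share a latent factor whose induced
#' pairwise correlation differs between conditions (differential wiring),
#' the module genes receive a log2 expression shift in the alternate
#' condition (differential expression), and all remaining genes/TFs are
#' independent noise.
#'
#' Defaults describe the stated validation world: 300 genes (20 of them the
#' planted module), 20 TFs, 50 samples per condition, within-condition
#' TF-module correlation 0.8 in condition 1 versus 0 in condition 2, a
#' 2-log2-fold DE shift, negative-binomial counts around a base mean of 100
#' with dispersion (size) 50, and a log2-scale biological noise standard
#' deviation of 1.
#'
#' @param n_genes total non-TF genes (module included).
#' @param n_tfs number of TFs; the first is the planted regulator.
#' @param n_samples_per_condition samples per condition.
#' @param planted_tf_rho length-2 vector: TF-module correlation in
#'   condition 1 and condition 2; each `|rho| < 1`.
#' @param planted_module_size number of module genes (`<= n_genes`).
#' @param de_effect log2 shift added to module genes in condition 2.
#' @param nb_dispersion negative-binomial size parameter; counts have
#'   variance `mu + mu^2 / nb_dispersion`.
#' @param base_mean baseline expression: the count-scale mean for
#'   [sim_counts()], the log2-scale baseline for [sim_norm()].
#' @param noise_sd per-gene, per-sample Gaussian noise SD on the log2 latent
#'   scale.
#' @param seed integer RNG seed; the same spec always yields bit-identical
#'   output.
#' @return an object of class `sim_spec`.
#' @export
sim_spec <- function(n_genes = 300, n_tfs = 20, n_samples_per_condition = 50,
                     planted_tf_rho = c(0.8, 0), planted_module_size = 20,
                     de_effect = 2, nb_dispersion = 50, base_mean = 100,
                     noise_sd = 1, seed = 1L) {
  stopifnot(n_genes >= 1, n_tfs >= 1, n_samples_per_condition >= 2,
            length(planted_tf_rho) == 2,
            planted_module_size >= 0, planted_module_size <= n_genes,
            nb_dispersion > 0, base_mean > 0, noise_sd >= 0)
  if (any(abs(planted_tf_rho) >= 1)) {
    stop("|planted_tf_rho| must be < 1 (a loading reproducing |rho| = 1 is infeasible)")
  }
  structure(as.list(environment()), class = "sim_spec")
}

# Shared latent-factor construction on the log2 scale. Returns the latent
# matrix plus ids/design/truth. Module genes and the planted TF load on one
# factor per sample with loading lambda_c = noise_sd * sqrt(|rho_c|/(1-|rho_c|)),
# which makes every pairwise correlation among them |rho_c|; a negative rho
# flips the sign of the TF loading only, so TF-gene correlations are rho_c.
# Module genes get +de_effect in condition 2.
sim_latent <- function(spec) {
  n_s <- 2L * spec$n_samples_per_condition
  gene_ids <- sprintf("G%04d", seq_len(spec$n_genes))
  tf_ids <- sprintf("TF%03d", seq_len(spec$n_tfs))
  sample_ids <- sprintf("S%04d", seq_len(n_s))
  cond <- rep(c("cond1", "cond2"), each = spec$n_samples_per_condition)
  module <- gene_ids[seq_len(spec$planted_module_size)]
  planted_tf <- tf_ids[1]

  all_ids <- c(gene_ids, tf_ids)
  lat <- matrix(stats::rnorm(length(all_ids) * n_s, sd = spec$noise_sd),
                nrow = length(all_ids), ncol = n_s,
                dimnames = list(all_ids, sample_ids))
  f <- stats::rnorm(n_s)                       # shared latent factor
  for (ci in 1:2) {
    rho <- spec$planted_tf_rho[ci]
    if (rho == 0) next
    # loading giving pairwise correlation |rho| on top of noise_sd noise;
    # with zero noise any positive loading is exact, use the unit-scale one
    scale <- if (spec$noise_sd > 0) spec$noise_sd else 1
    lam <- scale * sqrt(abs(rho) / (1 - abs(rho)))
    idx <- which(cond == c("cond1", "cond2")[ci])
    if (length(module)) {
      lat[module, idx] <- lat[module, idx] +
        rep(lam * f[idx], each = length(module))
    }
    lat[planted_tf, idx] <- lat[planted_tf, idx] + sign(rho) * lam * f[idx]
  }
  if (length(module) && spec$de_effect != 0) {
    idx2 <- which(cond == "cond2")
    lat[module, idx2] <- lat[module, idx2] + spec$de_effect
  }
  list(latent = lat, gene_ids = gene_ids, tf_ids = tf_ids,
       sample_ids = sample_ids, cond = cond,
       design = condition_design(stats::setNames(cond, sample_ids), "cond1"),
       truth = structure(list(planted_tf = planted_tf, module = module,
                              de_genes = module,
                              conditions = c("cond1", "cond2")),
                         class = "ground_truth"))
}

#' Simulate a negative-binomial count experiment with planted structure
#'
#' Counts are drawn NB with mean `base_mean * 2^signal` (signal the centered
#' latent log2 value) and size `nb_dispersion`, independently per cell; the
#' latent layer carries the planted correlation and DE structure described
#' in [sim_spec()].
#'
#' @param spec a [sim_spec()].
#' @return list with `matrix` (counts [expression_matrix()]), `design`
#'   ([condition_design()], reference `"cond1"`), `tfs` (TF catalog,
#'   character), `truth` (`ground_truth`: planted TF, module/DE gene ids,
#'   condition labels).
#' @export
sim_counts <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    parts <- sim_latent(spec)
    mu <- spec$base_mean * 2^parts$latent
    counts <- matrix(
      stats::rnbinom(length(mu), mu = as.vector(mu), size = spec$nb_dispersion),
      nrow = nrow(mu), dimnames = dimnames(mu))
    list(matrix = expression_matrix(counts, "counts"),
         design = parts$design, tfs = parts$tf_ids, truth = parts$truth)
  })
}

#' Simulate an already-normalized (log2-scale) experiment
#'
#' Emits the latent log2 expressions directly — `base_mean` plus the factor
#' signal plus Gaussian noise — skipping the count-sampling layer. With
#' `noise_sd = 0` the module rows are exact affine images of the latent
#' factor. Values are floored at 0 to honour the nonnegativity contract of
#' [expression_matrix()] (with the default `base_mean` far from 0 the floor
#' is essentially never hit).
#'
#' @param spec a [sim_spec()]; `base_mean` is interpreted on the log2 scale
#'   here (e.g. 8, not 100; the default count-scale 100 maps to usable but
#'   high values).
#' @return as [sim_counts()] but with `kind = "normalized"`.
#' @export
sim_norm <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    parts <- sim_latent(spec)
    vals <- pmax(parts$latent + spec$base_mean, 0)
    list(matrix = expression_matrix(vals, "normalized"),
         design = parts$design, tfs = parts$tf_ids, truth = parts$truth)
  })
}

#' Write a simulated dataset to a directory
#'
#' Writes `matrix.tsv`, `design.tsv`, `tfs.txt` and `truth.tsv`; the matrix
#' header comment records the generating seed.
#'
#' @param sim output of [sim_counts()] or [sim_norm()].
#' @param dir output directory (created if needed).
#' @param seed seed to record in the header.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat_path <- file.path(dir, "matrix.tsv")
  con <- file(mat_path, "w")
  writeLines(sprintf("# tfwire simulation seed=%s kind=%s",
                     as.character(seed), sim$matrix$kind), con)
  close(con)
  df <- data.frame(gene = sim$matrix$gene_ids, sim$matrix$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  suppressWarnings(utils::write.table(df, mat_path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  utils::write.table(
    data.frame(sample = names(sim$design$assignments),
               condition = unname(sim$design$assignments)),
    file.path(dir, "design.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  writeLines(sim$tfs, file.path(dir, "tfs.txt"))
  truth <- rbind(
    data.frame(role = "planted_tf", id = sim$truth$planted_tf),
    if (length(sim$truth$module))
      data.frame(role = "module", id = sim$truth$module),
    if (length(sim$truth$de_genes))
      data.frame(role = "de", id = sim$truth$de_genes)
  )
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
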