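# Shared fixtures and independent oracles. The naive PCIT below is kept
# deliberately dumb (scalar triple loop, its own partial-correlation
# arithmetic) so it can serve as an oracle for the compiled implementation.

toy_em <- function(vals, kind = "normalized",
                   genes = sprintf("g%d", seq_len(nrow(vals))),
                   samples = sprintf("s%d", seq_len(ncol(vals)))) {
  dimnames(vals) <- list(genes, samples)
  expression_matrix(vals, kind)
}

# Balanced two-condition design over the columns of an expression matrix.
toy_design <- function(m, reference = "A") {
  n <- length(m$sample_ids)
  stopifnot(n %% 2 == 0)
  condition_design(
    stats::setNames(rep(c("A", "B"), each = n / 2), m$sample_ids),
    reference)
}

# Random valid correlation matrix from n_obs draws of n variables.
rand_cor <- function(n, n_obs = n + 8) {
  r <- stats::cor(matrix(stats::rnorm(n_obs * n), n_obs, n))
  dimnames(r) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  r
}

# Independent PCIT oracle: plain R, scalar arithmetic, no shared code with
# the package's compiled loop.
naive_pcit <- function(r, corrected = TRUE) {
  n <- nrow(r)
  keep <- matrix(TRUE, n, n)
  diag(keep) <- FALSE
  if (n < 3) return(keep)
  pc <- function(a, b, c) (a - b * c) / sqrt((1 - b^2) * (1 - c^2))
  for (x in 1:(n - 2)) for (y in (x + 1):(n - 1)) for (z in (y + 1):n) {
    rxy <- r[x, y]; rxz <- r[x, z]; ryz <- r[y, z]
    if (rxy == 0 || rxz == 0 || ryz == 0) next
    pxy <- pc(rxy, rxz, ryz)
    pxz <- pc(rxz, rxy, ryz)
    pyz <- pc(ryz, rxy, rxz)
    eps <- (pxy / rxy + pxz / rxz + pyz / ryz) / 3
    if (corrected) {
      if (abs(rxy) <= abs(eps * rxz) && abs(rxy) <= abs(eps * ryz))
        keep[x, y] <- keep[y, x] <- FALSE
      if (abs(rxz) <= abs(eps * rxy) && abs(rxz) <= abs(eps * ryz))
        keep[x, z] <- keep[z, x] <- FALSE
      if (abs(ryz) <= abs(eps * rxy) && abs(ryz) <= abs(eps * rxz))
        keep[y, z] <- keep[z, y] <- FALSE
    } else {
      if (abs(rxz) <= abs(eps * rxz) && abs(rxy) <= abs(eps * ryz))
        keep[x, y] <- keep[y, x] <- FALSE
      if (abs(rxy) <= abs(eps * rxy) && abs(rxz) <= abs(eps * ryz))
        keep[x, z] <- keep[z, x] <- FALSE
      if (abs(rxy) <= abs(eps * rxy) && abs(ryz) <= abs(eps * rxz))
        keep[y, z] <- keep[z, y] <- FALSE
    }
  }
  keep
}

# Hand-rolled condition_network for graph-summary tests.
toy_net <- function(edges, nodes = NULL, tfs = character(),
                    condition = "test") {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  structure(list(
    nodes = data.frame(id = nodes,
                       role = ifelse(nodes %in% tfs, "TF", "gene"),
                       stringsAsFactors = FALSE),
    edges = edges,
    condition = condition
  ), class = "condition_network")
}

edge_df <- function(a = character(), b = character(), w = 1) {
  data.frame(node_a = a, node_b = b,
             weight = rep_len(w, length(a)), stringsAsFactors = FALSE)
}

# Minimal hand-built de_classification / rif_table, for tests that need to
# bypass upstream stages (both are documented plain data frames).
make_declass <- function(gene, diff, status, is_tf = FALSE, cutoff = 1.96) {
  out <- data.frame(gene = gene, diff = diff, avgexpr = abs(diff) + 1,
                    status = status, is_tf = rep_len(is_tf, length(gene)),
                    stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("de_classification", "data.frame")
  out
}

make_rif_table <- function(TF, RIF1, RIF2, cutoff = 1.96) {
  out <- data.frame(TF = TF, avgexpr = 1, RIF1 = RIF1, RIF2 = RIF2,
                    rif1_raw = RIF1, rif2_raw = RIF2,
                    sig1 = abs(RIF1) > cutoff, sig2 = abs(RIF2) > cutoff,
                    stringsAsFactors = FALSE)
  attr(out, "sig_cutoff") <- cutoff
  class(out) <- c("rif_table", "data.frame")
  out
}
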