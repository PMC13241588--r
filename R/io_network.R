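#' Write a StreamNetwork as plain-text tables
#'
#' Four CSVs in a directory: nodes (id, x, y), edges (from, to, length),
#' sections (section, midpoint_node) and populations (pop_id, mouth_node,
#' point_node).
#'
#' @param net a \linkS4class{StreamNetwork}
#' @param dir output directory (created if needed)
#' @export
writeStreamNetwork <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) write.table(df, file.path(dir, f), sep = ",",
                                    quote = FALSE, row.names = FALSE)
  wr(net@nodes, "nodes.csv")
  wr(net@edges, "edges.csv")
  wr(net@sections, "sections.csv")
  wr(net@populations, "populations.csv")
  wr(data.frame(node = net@main_stem), "main_stem.csv")
  invisible(dir)
}

#' Read a StreamNetwork written by \code{\link{writeStreamNetwork}}
#'
#' @param dir directory containing the network CSVs
#' @return a \linkS4class{StreamNetwork}
#' @export
readStreamNetwork <- function(dir) {
  rd <- function(f) read.table(file.path(dir, f), header = TRUE, sep = ",",
                               stringsAsFactors = FALSE,
                               colClasses = NA)
  new("StreamNetwork", nodes = rd("nodes.csv"), edges = rd("edges.csv"),
      sections = rd("sections.csv"), populations = rd("populations.csv"),
      main_stem = rd("main_stem.csv")$node)
}

#' Write a simulated riverscape to plain-text files
#'
#' Emits everything a file-based pipeline run needs: one genotype table
#' holding baseline and mixture individuals, the covariate table (with the
#' simulation-truth columns), the true contribution array in long form, the
#' network tables, and a run-metadata file recording the seed and
#' configuration.
#'
#' @param sim output of \code{\link{simulateRiverscape}}
#' @param dir output directory
#' @return the directory, invisibly
#' @export
writeRiverscape <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all <- GenotypeMatrix(
    rbind(sim$baseline@allele1, sim$mixture@allele1),
    rbind(sim$baseline@allele2, sim$mixture@allele2),
    .rbind_info(sampleInfo(sim$baseline), sampleInfo(sim$mixture)))
  writeGenotypeTable(all, file.path(dir, "genotypes.csv"))
  write.table(sim$truth, file.path(dir, "covariates.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  ctr <- sim$contributions$contributions
  long <- expand.grid(pop_id = dimnames(ctr)[[1]],
                      section = dimnames(ctr)[[2]],
                      year = dimnames(ctr)[[3]], stringsAsFactors = FALSE)
  long$p_true <- as.vector(ctr)
  write.table(long, file.path(dir, "true_contributions.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  writeStreamNetwork(sim$network, file.path(dir, "network"))
  cfg <- sim$config
  cfg$zib_coefficients <- unclass(cfg$zib_coefficients)
  meta <- c(sprintf("seed: %d", cfg$seed),
            utils::capture.output(utils::str(cfg, give.attr = FALSE)))
  writeLines(meta, file.path(dir, "run_metadata.txt"))
  invisible(dir)
}
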