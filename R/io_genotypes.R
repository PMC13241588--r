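#' Construct a GenotypeMatrix from allele matrices
#'
#' @param allele1,allele2 character matrices (individuals x loci), \code{NA}
#'   for missing; column names are locus names.
#' @param info data.frame with columns \code{individual_id},
#'   \code{collection_id}, \code{role}, \code{section}, \code{year}.
#' @return a \linkS4class{GenotypeMatrix}
#' @export
GenotypeMatrix <- function(allele1, allele2, info) {
  allele1 <- as.matrix(allele1); allele2 <- as.matrix(allele2)
  mode(allele1) <- "character"; mode(allele2) <- "character"
  for (col in c("section")) if (is.null(info[[col]])) info[[col]] <- NA_character_
  if (is.null(info$year)) info$year <- NA_integer_
  rownames(allele1) <- rownames(allele2) <- info$individual_id
  new("GenotypeMatrix", allele1 = allele1, allele2 = allele2,
      info = as.data.frame(info, stringsAsFactors = FALSE))
}

.meta_cols <- c("individual_id", "collection_id", "role", "section", "year")

#' Read a two-column-per-locus genotype table
#'
#' The expected dialect is a single header row with the metadata columns
#' \code{individual_id}, \code{collection_id}, \code{role}, \code{section},
#' \code{year}, followed by two columns per locus named \code{<locus>} and
#' \code{<locus>.1}. A missing allele is an empty field or \code{"0"}; a
#' missing genotype must be missing in both columns. The delimiter (comma or
#' tab) is autodetected from the header line.
#'
#' @param path file path
#' @param exclude optional character vector of individual ids to drop on read
#'   (e.g. individuals independently identified as hybrids).
#' @return a \linkS4class{GenotypeMatrix}
#' @export
readGenotypeTable <- function(path, exclude = character()) {
  stopifnot(file.exists(path))
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, colClasses = "character",
                   check.names = FALSE, na.strings = c("", "0", "NA"))
  if (!all(.meta_cols %in% names(df)))
    stop("genotype table must start with columns: ",
         paste(.meta_cols, collapse = ", "))
  gcols <- setdiff(names(df), .meta_cols)
  if (length(gcols) %% 2 != 0)
    stop("malformed genotype table: odd number of allele columns (",
         length(gcols), ")")
  loci <- gcols[seq(1, length(gcols), by = 2)]
  second <- gcols[seq(2, length(gcols), by = 2)]
  if (!all(second == paste0(loci, ".1")))
    stop("allele columns must come in '<locus>', '<locus>.1' pairs")
  if (anyDuplicated(df$individual_id))
    stop("duplicate individual_id in genotype table")
  a1 <- as.matrix(df[, loci, drop = FALSE])
  a2 <- as.matrix(df[, second, drop = FALSE])
  colnames(a2) <- loci
  # missing is all-or-nothing: a half-missing call is treated as missing
  half <- is.na(a1) != is.na(a2)
  if (any(half)) {
    rg_warn("%d half-missing calls set to missing", sum(half))
    a1[half] <- NA; a2[half] <- NA
  }
  info <- df[, .meta_cols]
  info$year <- suppressWarnings(as.integer(info$year))
  G <- GenotypeMatrix(a1, a2, info)
  if (length(exclude)) G <- G[!(G@info$individual_id %in% exclude), ]
  G
}

#' Write a GenotypeMatrix in the two-column-per-locus dialect
#'
#' @param G a \linkS4class{GenotypeMatrix}
#' @param path output file path
#' @param sep field delimiter ("," or "\t")
#' @param missing_code code written for a missing allele (default "0")
#' @export
writeGenotypeTable <- function(G, path, sep = ",", missing_code = "0") {
  L <- nLoci(G)
  out <- G@info[, .meta_cols]
  geno <- matrix("", nrow = nIndividuals(G), ncol = 2L * L)
  geno[, seq(1, 2 * L, by = 2)] <- ifelse(is.na(G@allele1), missing_code, G@allele1)
  geno[, seq(2, 2 * L, by = 2)] <- ifelse(is.na(G@allele2), missing_code, G@allele2)
  cn <- character(2L * L)
  cn[seq(1, 2 * L, by = 2)] <- locusNames(G)
  cn[seq(2, 2 * L, by = 2)] <- paste0(locusNames(G), ".1")
  geno <- as.data.frame(geno, stringsAsFactors = FALSE)
  names(geno) <- cn
  write.table(cbind(out, geno), path, sep = sep, quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Retain individuals genotyped at a minimum fraction of loci
#'
#' @param G a \linkS4class{GenotypeMatrix}
#' @param min_rate minimum fraction of loci with a non-missing call
#'   (default 0.85); individuals with call rate >= \code{min_rate} are kept,
#'   in their original order.
#' @return filtered \linkS4class{GenotypeMatrix}
#' @export
filterByCallRate <- function(G, min_rate = 0.85) {
  stopifnot(min_rate > 0 || min_rate == 0, min_rate <= 1)
  keep <- callRate(G) >= min_rate
  if (!any(keep)) rg_warn("call-rate filter removed every individual")
  G[keep, ]
}

#' Describe a locus panel for filtering
#'
#' @param locus_names character vector of locus names
#' @param species_diagnostic,mitochondrial character vectors naming flagged
#'   loci
#' @return data.frame with columns \code{locus_name}, \code{flagged_class}
#' @export
locusPanel <- function(locus_names, species_diagnostic = character(),
                       mitochondrial = character()) {
  fc <- rep("none", length(locus_names))
  fc[locus_names %in% species_diagnostic] <- "species_diagnostic"
  fc[locus_names %in% mitochondrial] <- "mitochondrial"
  data.frame(locus_name = locus_names, flagged_class = fc,
             stringsAsFactors = FALSE)
}

#' Drop flagged and invariant loci
#'
#' Removes loci flagged as species-diagnostic or mitochondrial in the panel,
#' plus loci with fewer than two observed alleles across the retained
#' individuals (assessed on the union of baseline and mixture individuals,
#' after any individual filtering).
#'
#' @param G a \linkS4class{GenotypeMatrix}
#' @param panel data.frame from \code{\link{locusPanel}} covering all loci in
#'   \code{G}
#' @return list with \code{genotypes} (filtered \code{GenotypeMatrix}) and
#'   \code{report} (data.frame of removed loci and reasons)
#' @export
dropLoci <- function(G, panel) {
  ln <- locusNames(G)
  if (!all(ln %in% panel$locus_name))
    stop("panel does not cover all loci in the genotype matrix")
  flag <- panel$flagged_class[match(ln, panel$locus_name)]
  n_alleles <- vapply(seq_along(ln), function(j) {
    length(unique(na.omit(c(G@allele1[, j], G@allele2[, j]))))
  }, integer(1))
  reason <- rep(NA_character_, length(ln))
  reason[n_alleles < 2] <- "invariant"
  reason[flag == "mitochondrial"] <- "mitochondrial"
  reason[flag == "species_diagnostic"] <- "species_diagnostic"
  drop <- !is.na(reason)
  list(genotypes = G[, !drop],
       report = data.frame(locus_name = ln[drop], reason = reason[drop],
                           stringsAsFactors = FALSE))
}

#' Reference-allele dosage representation of a GenotypeMatrix
#'
#' For each locus the reference allele is the lexicographically first observed
#' allele code (or the first of \code{alleles$ref} if supplied). Returns the
#' dosage matrix (copies of the reference allele: 0, 1, 2 or NA) and the
#' allele labels, which downstream allele-frequency machinery consumes.
#'
#' @param G a \linkS4class{GenotypeMatrix}
#' @param alleles optional data.frame \code{locus}, \code{ref}, \code{alt}
#'   fixing the allele labelling (e.g. from a \code{BaselineUnits} object)
#' @return list: \code{dosage} (individuals x loci integer matrix),
#'   \code{alleles} (data.frame locus/ref/alt)
#' @export
refDosage <- function(G, alleles = NULL) {
  ln <- locusNames(G)
  if (is.null(alleles)) {
    ref <- alt <- character(length(ln))
    for (j in seq_along(ln)) {
      lev <- sort(unique(na.omit(c(G@allele1[, j], G@allele2[, j]))))
      ref[j] <- if (length(lev)) lev[1] else "1"
      alt[j] <- if (length(lev) > 1) lev[2] else ""
    }
    alleles <- data.frame(locus = ln, ref = ref, alt = alt,
                          stringsAsFactors = FALSE)
  } else {
    alleles <- alleles[match(ln, alleles$locus), ]
    if (any(is.na(alleles$ref))) stop("allele table does not cover all loci")
  }
  refm <- matrix(alleles$ref, nrow = nIndividuals(G), ncol = length(ln),
                 byrow = TRUE)
  d <- (G@allele1 == refm) + (G@allele2 == refm)
  mode(d) <- "integer"
  dimnames(d) <- list(G@info$individual_id, ln)
  list(dosage = d, alleles = alleles)
}
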