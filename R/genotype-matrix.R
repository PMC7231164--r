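#' Construct a genotype matrix object
#'
#' The central container of the package: biallelic SNP calls for a cohort of
#' individuals split into a pre-selection baseline group and two
#' post-selection groups (e.g. larvae, brackish juveniles, marine juveniles).
#' Calls are coded as copies of the reference allele (0, 1, 2) with `NA` for
#' missing genotypes.
#'
#' @param calls integer matrix, individuals in rows and loci in columns, each
#'   entry 0/1/2 or `NA`. Row names are individual ids, column names locus ids.
#' @param groups character or factor of group labels, one per individual,
#'   either named by individual id or in row order of `calls`.
#' @param tags optional character vector of tag-of-origin ids (e.g. RAD-tag),
#'   one per locus; loci sharing a tag are treated as one effective test in
#'   Bonferroni corrections.
#' @param ref_depth,alt_depth optional integer matrices of per-call allele
#'   read depths, same dimensions as `calls`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `groups` (factor named by individual), `tags`, `ref_depth`,
#'   `alt_depth`.
#' @export
genotype_matrix <- function(calls, groups, tags = NULL,
                            ref_depth = NULL, alt_depth = NULL) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)) && nrow(calls) > 0) {
    rownames(calls) <- paste0("ind", seq_len(nrow(calls)))
  }
  if (is.null(colnames(calls)) && ncol(calls) > 0) {
    colnames(calls) <- paste0("locus", seq_len(ncol(calls)))
  }
  if (anyDuplicated(colnames(calls))) {
    stop("locus ids must be unique")
  }
  if (anyDuplicated(rownames(calls))) {
    stop("individual ids must be unique")
  }
  storage.mode(calls) <- "integer"
  bad <- !(calls %in% c(0L, 1L, 2L, NA))
  if (any(bad, na.rm = TRUE)) {
    stop("genotype calls must be 0, 1, 2 or NA")
  }
  if (!is.null(names(groups))) {
    missing_ids <- setdiff(rownames(calls), names(groups))
    if (length(missing_ids)) {
      stop("no group label for individual(s): ",
           paste(utils::head(missing_ids, 5), collapse = ", "))
    }
    groups <- groups[rownames(calls)]
  } else if (length(groups) != nrow(calls)) {
    stop("length of 'groups' must equal the number of individuals")
  }
  groups <- factor(as.character(groups))
  names(groups) <- rownames(calls)
  if (!is.null(tags)) {
    if (length(tags) != ncol(calls)) {
      stop("length of 'tags' must equal the number of loci")
    }
    tags <- as.character(tags)
    names(tags) <- colnames(calls)
  }
  for (d in list(ref_depth, alt_depth)) {
    if (!is.null(d) && !identical(dim(d), dim(calls))) {
      stop("allele depth matrices must have the same dimensions as 'calls'")
    }
  }
  structure(
    list(calls = calls, groups = groups, tags = tags,
         ref_depth = ref_depth, alt_depth = alt_depth),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "individuals x",
      ncol(x$calls), "loci\n")
  tab <- table(x$groups)
  cat("groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("missing calls: %.2f%%", 100 * miss))
  if (!is.null(x$ref_depth)) cat("; allele depths attached")
  if (!is.null(x$tags)) {
    cat(";", length(unique(x$tags)), "tags")
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by loci and/or individuals
#'
#' @param G a `genotype_matrix`.
#' @param loci locus ids or column indices to keep (default all).
#' @param individuals individual ids or row indices to keep (default all).
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(G, loci = NULL, individuals = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  li <- if (is.null(loci)) seq_len(ncol(G$calls)) else loci
  ii <- if (is.null(individuals)) seq_len(nrow(G$calls)) else individuals
  sub_mat <- function(m) if (is.null(m)) NULL else m[ii, li, drop = FALSE]
  calls <- G$calls[ii, li, drop = FALSE]
  genotype_matrix(
    calls,
    groups = G$groups[rownames(calls)],
    tags = if (is.null(G$tags)) NULL else G$tags[colnames(calls)],
    ref_depth = sub_mat(G$ref_depth),
    alt_depth = sub_mat(G$alt_depth)
  )
}

group_ids <- function(G, group) {
  ids <- names(G$groups)[G$groups == group]
  if (!length(ids)) stop("no individuals in group '", group, "'")
  ids
}

read_group_map <- function(group_map) {
  if (is.character(group_map) && length(group_map) == 1) {
    group_map <- utils::read.table(group_map, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
  }
  group_map <- as.data.frame(group_map)
  if (ncol(group_map) < 2) {
    stop("group map needs two columns: individual id and group label")
  }
  stats::setNames(as.character(group_map[[2]]), as.character(group_map[[1]]))
}

#' Load genotypes from a VCF or delimited matrix file
#'
#' VCF genotypes (GT field) are decoded as counts of the REF allele, so
#' `0/0 -> 2`, `0/1 -> 1`, `1/1 -> 0` and `./.` -> `NA`. When an AD field is
#' present, per-call reference/alternate read depths are attached (used by
#' [allele_balance_filter()]). Multiallelic records are skipped with a
#' message. The matrix format is a tab-delimited table with individuals in
#' rows (first column = id), locus ids in the header, and values 0/1/2/NA.
#'
#' @param path path to the input file.
#' @param format `"vcf"`, `"matrix"`, or `"auto"` (by file extension).
#' @param group_map two-column data frame (id, group) or path to a
#'   tab-delimited file with header columns `id` and `group`. Must cover all
#'   individuals in the file; unknown individuals are an error.
#' @return A [genotype_matrix()].
#' @export
load_genotypes <- function(path, format = c("auto", "vcf", "matrix"),
                           group_map) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "matrix"
  }
  groups <- read_group_map(group_map)
  if (format == "vcf") {
    g <- load_genotypes_vcf(path)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             row.names = 1, check.names = FALSE)
    g <- list(calls = as.matrix(tab), tags = NULL,
              ref_depth = NULL, alt_depth = NULL)
  }
  unknown <- setdiff(rownames(g$calls), names(groups))
  if (length(unknown)) {
    stop("individual(s) absent from group map: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  genotype_matrix(g$calls, groups = groups[rownames(g$calls)], tags = g$tags,
                  ref_depth = g$ref_depth, alt_depth = g$alt_depth)
}

load_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  alt <- fix[, "ALT"]
  biallelic <- !grepl(",", alt) & alt != "." & !is.na(alt)
  n_skip <- sum(!biallelic)
  if (n_skip > 0) {
    message(n_skip, " non-biallelic record(s) skipped")
    vcf <- vcf[biallelic, ]
    fix <- vcfR::getFIX(vcf)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # count REF alleles in the GT string; tolerate phased separators
  ref_count <- function(s) {
    out <- rep(NA_integer_, length(s))
    ok <- !is.na(s) & !grepl("\\.", s)
    alleles <- strsplit(gsub("\\|", "/", s[ok]), "/")
    out[ok] <- vapply(alleles, function(a) sum(a == "0"), integer(1))
    out
  }
  calls <- apply(gt, 2, ref_count)
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = nrow(gt))
  rn <- fix[, "ID"]
  if (any(is.na(rn) | rn == ".")) {
    rn <- paste0(fix[, "CHROM"], "_", fix[, "POS"])
  }
  calls <- t(calls)  # -> individuals x loci
  colnames(calls) <- rn
  # tag-of-origin: CHROM doubles as the RAD-tag id for stacks-style exports
  tags <- fix[, "CHROM"]
  ref_depth <- alt_depth <- NULL
  if ("AD" %in% vcfR::vcf_field_names(vcf, tag = "FORMAT")$ID) {
    ad <- vcfR::extract.gt(vcf, element = "AD")
    split_ad <- function(s, i) {
      out <- rep(NA_integer_, length(s))
      ok <- !is.na(s)
      parts <- strsplit(s[ok], ",")
      out[ok] <- suppressWarnings(
        as.integer(vapply(parts, `[`, character(1), i))
      )
      out
    }
    ref_depth <- t(apply(ad, 2, split_ad, i = 1L))
    alt_depth <- t(apply(ad, 2, split_ad, i = 2L))
    dimnames(ref_depth) <- dimnames(alt_depth) <- dimnames(calls)
  }
  list(calls = calls, tags = tags,
       ref_depth = ref_depth, alt_depth = alt_depth)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a plain-text VCFv4.2 with GT (and AD when depths are attached),
#' one biallelic record per locus. Locus tags, when present, are written as
#' the CHROM column so tag grouping round-trips.
#'
#' @param G a `genotype_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  ids <- rownames(G$calls)
  loci <- colnames(G$calls)
  has_ad <- !is.null(G$ref_depth)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sgselect",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_ad)
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele read depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  chrom <- if (is.null(G$tags)) loci else G$tags[loci]
  gt_code <- c(`0` = "1/1", `1` = "0/1", `2` = "0/0")
  lines <- vapply(seq_along(loci), function(j) {
    g <- G$calls[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    if (has_ad) {
      ad <- ifelse(is.na(G$ref_depth[, j]) | is.na(g), ".",
                   paste(G$ref_depth[, j], G$alt_depth[, j], sep = ","))
      samp <- paste(gt, ad, sep = ":")
      fmt <- "GT:AD"
    } else {
      samp <- gt
      fmt <- "GT"
    }
    paste(c(chrom[j], j, loci[j], "A", "C", ".", "PASS", ".", fmt, samp),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write a genotype matrix as a delimited 0/1/2 table
#'
#' @param G a `genotype_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_matrix <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  df <- data.frame(id = rownames(G$calls), G$calls, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the group map of a genotype matrix
#'
#' @param G a `genotype_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_group_map <- function(G, path) {
  df <- data.frame(id = names(G$groups), group = as.character(G$groups))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
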