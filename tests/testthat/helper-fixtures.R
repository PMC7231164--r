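# small in-code fixtures shared across test files

# genotype matrix with explicit calls and equal-sized groups
make_G <- function(calls, groups, ...) {
  genotype_matrix(as.matrix(calls), groups = groups, ...)
}

# a three-group matrix of independent HWE draws from shared frequencies
make_null_G <- function(n_per_group = c(baseline = 20, groupA = 30,
                                        groupB = 30),
                        p = c(0.5, 0.2, 0.8), seed = 1) {
  set.seed(seed)
  n <- sum(n_per_group)
  calls <- vapply(p, function(pp) rbinom(n, 2, pp), numeric(n))
  make_G(calls, groups = rep(names(n_per_group), n_per_group))
}

# minimal VCF text fixture: 3 individuals, 2 biallelic loci + 1 triallelic
write_tiny_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("tag1", "10", "snp1", "A", "C", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("tag1", "40", "snp2", "G", "T", ".", "PASS", ".", "GT",
          "0/1", "./.", "0/0", sep = "\t"),
    paste("tag2", "12", "snp3", "G", "T,A", ".", "PASS", ".", "GT",
          "0/1", "1/2", "0/0", sep = "\t")
  ), path)
  path
}
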