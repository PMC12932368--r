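#' Export genotypes as a VCF file
#'
#' Writes a minimal phased VCF (v4.2) of the population's loci. The
#' simulation tracks abstract biallelic sites without nucleotide identities,
#' so REF/ALT are written as the placeholders `A`/`T`; positions are the
#' physical bp positions implied by the uniform bp-to-cM map.
#'
#' @param pop a `haplo_pop` (heterozygous, phased) or `line_pop`
#'   (homozygous).
#' @param path output file path.
#' @param role which loci to export (`"all"`, `"QTN"`, `"SNP"`).
#' @return the path, invisibly.
#' @export
write_vcf <- function(pop, path, role = "all") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=sparsecross",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", pop$ids), collapse = "\t")), con)
  diploid <- inherits(pop, "haplo_pop")
  cm_per_bp <- if (!is.null(pop$params)) {
    pop$params$chr_length_cM / pop$params$chr_length_bp
  } else {
    1e-6
  }
  for (chr in seq_along(pop$haps)) {
    h <- pop$haps[[chr]]
    keep <- if (role == "all") seq_len(nrow(h)) else
      which(pop$role[[chr]] == role)
    if (!length(keep)) next
    pos_bp <- round(pop$pos[[chr]][keep] / cm_per_bp)
    for (ii in seq_along(keep)) {
      l <- keep[ii]
      gt <- if (diploid) {
        a <- h[l, ]
        paste(a[c(TRUE, FALSE)], a[c(FALSE, TRUE)], sep = "|")
      } else {
        paste(h[l, ], h[l, ], sep = "|")
      }
      writeLines(paste(c(chr, pos_bp[ii],
                         sprintf("chr%d_%d", chr, l), "A", "T", ".", "PASS",
                         ".", "GT", gt), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Export a trait architecture as a delimited table
#'
#' @param trait a `trait_arch`.
#' @param path output path.
#' @param sep field separator.
#' @return the path, invisibly.
#' @export
write_trait_table <- function(trait, path, sep = "\t") {
  df <- data.frame(chrom = trait$chr, pos = trait$pos, a = trait$a,
                   delta = trait$delta, d = trait$d)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a testcross assignment as a delimited table
#'
#' @param assignment a `testcross_assignment`.
#' @param path output path.
#' @param cycle optional cycle index column.
#' @param sep field separator.
#' @return the path, invisibly.
#' @export
write_assignment <- function(assignment, path, cycle = NA, sep = "\t") {
  df <- data.frame(line_id = assignment$line_id,
                   tester_id = assignment$tester_id,
                   design_name = attr(assignment, "design_name"),
                   cycle = cycle)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build an experiment configuration from a YAML file
#'
#' The file holds a flat mapping mirroring the arguments of
#' [experiment_config()] (e.g. `scenario`, `designs`, `n_cycles`,
#' `n_replicates`, `scale`, `root_seed`, plus any profile overrides).
#'
#' @param path YAML file path.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read configuration files")
  }
  do.call(experiment_config, yaml::read_yaml(path))
}
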