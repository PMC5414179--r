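#' Write a genotype matrix as a minimal GT-only VCF
#'
#' Writes VCFv4.2 with 1-based positions, unphased GT calls derived from the
#' additive coding (0 -> 0/0, 1 -> 0/1, 2 -> 1/1, NA -> ./.) and per-variant
#' `MAF=` / `IMPINFO=` INFO keys.
#'
#' @param G a [genotype_matrix()].
#' @param path output file.
#' @export
write_genotypes_vcf <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  v <- G$variants
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- apply(G$genotypes, 2, function(col) {
    out <- gt_code[as.character(col)]
    out[is.na(col)] <- "./."
    out
  })
  gt <- matrix(gt, nrow = nrow(G$genotypes))  # samples x variants
  info <- sprintf("MAF=%s%s", format(v$maf, trim = TRUE, digits = 10),
                  ifelse(is.null(v$info) | is.na(v$info), "",
                         sprintf(";IMPINFO=%s",
                                 format(v$info, trim = TRUE, digits = 10))))
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
              "##INFO=<ID=IMPINFO,Number=1,Type=Float,Description=\"Imputation information score\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", G$sample_ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(k) {
    paste(c(v$chrom[k], v$pos[k], v$id[k], v$ref[k], v$alt[k], ".", ".",
            info[k], "GT", gt[, k]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a genotype matrix as TSV
#'
#' One row per variant: metadata columns (`id`, `chrom`, `pos`, `ref`,
#' `alt`, `maf`, `info`) followed by one column per sample holding the
#' additive genotype; missing is written as ".".
#'
#' @param G a [genotype_matrix()].
#' @param path output file.
#' @export
write_genotypes_tsv <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  v <- G$variants
  if (is.null(v$info)) v$info <- NA_real_
  gt <- t(G$genotypes)
  df <- data.frame(v[, c("id", "chrom", "pos", "ref", "alt", "maf", "info")],
                   gt, check.names = FALSE)
  colnames(df)[-(1:7)] <- G$sample_ids
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Read a genotype matrix from minimal VCF or TSV
#'
#' VCF is parsed via the vcfR package (GT field only; `./.` becomes NA;
#' `MAF=` and `IMPINFO=` INFO keys populate the variant metadata, with MAF
#' recomputed from the genotypes when the key is absent). The TSV dialect is
#' the one written by [write_genotypes_tsv()]. Writing then reading a matrix
#' reproduces it exactly.
#'
#' @param path input file.
#' @param format `"auto"` (by extension / leading `##fileformat`), `"vcf"`
#'   or `"tsv"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (startsWith(first, "##fileformat=VCF") || grepl("\\.vcf$", path))
      "vcf" else "tsv"
  }
  if (format == "vcf") .read_genotypes_vcf(path) else .read_genotypes_tsv(path)
}

.read_genotypes_vcf <- function(path) {
  .validate_vcf_structure(path)
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) stop("no variant records in VCF: ", path)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  ploidy <- nchar(gsub("[^0-9.]", "", gt_raw[!is.na(gt_raw)]))
  if (length(ploidy) && any(ploidy != 2)) {
    stop("mixed or non-diploid ploidy in VCF genotypes")
  }
  dose <- apply(gt_raw, 2, function(col) {
    a <- substr(col, 1, 1); b <- substr(col, 3, 3)
    out <- suppressWarnings(as.integer(a) + as.integer(b))
    out
  })
  dose <- matrix(dose, nrow = nrow(fix))
  info_field <- function(key) {
    m <- regmatches(fix$INFO, regexpr(paste0(key, "=[-0-9.eE+]+"), fix$INFO))
    out <- rep(NA_real_, nrow(fix))
    hit <- grepl(paste0(key, "="), fix$INFO)
    out[hit] <- as.numeric(sub(paste0(key, "="), "",
                               regmatches(fix$INFO,
                                          regexpr(paste0(key, "=[-0-9.eE+]+"),
                                                  fix$INFO))))
    out
  }
  maf <- info_field("MAF")
  if (anyNA(maf)) {
    af <- rowMeans(dose, na.rm = TRUE) / 2
    maf[is.na(maf)] <- pmin(af, 1 - af)[is.na(maf)]
  }
  variants <- data.frame(id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT, maf = maf, info = info_field("IMPINFO"),
                         stringsAsFactors = FALSE)
  genotype_matrix(t(dose), variants, sample_ids = colnames(gt_raw))
}

# structural pre-check with line numbers; malformed files must raise a plain
# R error rather than reach the low-level VCF parser
.validate_vcf_structure <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM\t", lines)
  if (!length(hdr)) {
    stop(sprintf("malformed VCF '%s': no #CHROM header line", path))
  }
  n_fields <- length(strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]])
  if (n_fields < 10) {
    stop(sprintf("malformed VCF '%s' at line %d: header carries no FORMAT/sample columns",
                 path, hdr[1]))
  }
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  if (!length(body)) {
    stop(sprintf("malformed VCF '%s': no variant records after line %d",
                 path, hdr[1]))
  }
  widths <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[widths != n_fields]
  if (length(bad)) {
    stop(sprintf("malformed VCF '%s' at line %d: %d fields where %d expected",
                 path, bad[1], widths[body == bad[1]][1], n_fields))
  }
  invisible(TRUE)
}

.read_genotypes_tsv <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, check.names = FALSE, na.strings = ".",
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed genotype TSV '", path, "': ",
                             conditionMessage(e)))
  meta_cols <- c("id", "chrom", "pos", "ref", "alt", "maf", "info")
  if (!all(meta_cols %in% names(df))) {
    stop("genotype TSV must carry columns: ", paste(meta_cols, collapse = ", "))
  }
  sample_ids <- setdiff(names(df), meta_cols)
  if (!length(sample_ids)) stop("genotype TSV has no sample columns")
  gt <- t(as.matrix(df[, sample_ids, drop = FALSE]))
  bad <- which(matrix(!(gt %in% c(0, 1, 2, NA)), nrow = nrow(gt)),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("malformed genotype value at line %d of '%s'",
                 bad[1, 2] + 1L, path))
  }
  storage.mode(gt) <- "integer"
  genotype_matrix(gt, df[, meta_cols], sample_ids = sample_ids)
}

#' Read a long-format Ct table
#'
#' Expects tab-separated columns `sample`, `target`, `allele`, `condition`,
#' `replicate`, `ct` and optionally `template`; "." marks a missing allele.
#'
#' @param path input TSV.
#' @return data.frame ready for the qPCR analysis functions.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, na.strings = ".", stringsAsFactors = FALSE)
  .check_ct(df)
  df
}

#' Write a data.frame as TSV (".", for missing)
#' @param df data.frame.
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}
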