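#' Read a methylation beta matrix from TSV
#'
#' First column holds probe ids, the header row sample ids; cells are
#' numeric betas in \eqn{[0,1]} or \code{NA}.
#'
#' @param path TSV file path.
#' @param annotation optional probe annotation (data.frame or GRanges), see
#'   \code{\link{MethylationExperiment}}.
#' @param covariates optional covariate table.
#' @return A \linkS4class{MethylationExperiment}.
#' @export
readMethylation <- function(path, annotation = NULL, covariates = NULL) {
    hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
    if (length(hdr) < 2L)
        stop("malformed header: expected probe-id column plus sample columns")
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character")
    ids <- tab[[1L]]
    if (anyDuplicated(ids))
        stop("duplicate probe ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(tab[, -1L, drop = FALSE])
    suppressWarnings(storage.mode(m) <- "double")
    bad_chr <- is.na(m) & tab[, -1L, drop = FALSE] != "NA" &
        !is.na(as.matrix(tab[, -1L, drop = FALSE]))
    rownames(m) <- ids
    out <- !is.na(m) & (m < -.BETA_TOL | m > 1 + .BETA_TOL)
    if (any(out)) {
        i <- which(out, arr.ind = TRUE)[1L, ]
        stop(sprintf("beta outside [0,1] at probe '%s', sample '%s': %s",
                     ids[i[1L]], colnames(m)[i[2L]], m[i[1L], i[2L]]))
    }
    MethylationExperiment(m, annotation = annotation, covariates = covariates)
}

#' Write a beta matrix to TSV (6 decimal places)
#'
#' @param x a \code{MethylationExperiment} or numeric matrix.
#' @param path output path.
#' @param digits decimals kept in the file (declared precision of the
#'   format; round-trips are exact at this precision).
#' @export
writeMethylation <- function(x, path, digits = 6) {
    m <- if (is(x, "MethylationExperiment")) betas(x) else as.matrix(x)
    fm <- matrix(sprintf(paste0("%.", digits, "f"), m), nrow = nrow(m))
    fm[is.na(m)] <- "NA"
    lines <- c(paste(c("probe_id", colnames(m)), collapse = "\t"),
               paste(rownames(m), apply(fm, 1L, paste, collapse = "\t"),
                     sep = "\t"))
    writeLines(lines, path)
    invisible(path)
}

#' Read / write a covariate table
#'
#' One row per sample; a \code{sample_id} column is required and must be
#' unique. \code{arm}, \code{sex}, \code{batch}, \code{season} and
#' \code{cohort} are read as factors when present.
#' @param path TSV path.
#' @return data.frame with \code{sample_id} rownames.
#' @export
readCovariates <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(df)) stop("covariate table needs sample_id")
    if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
    for (col in c("arm", "sex", "batch", "season", "cohort"))
        if (col %in% names(df)) df[[col]] <- factor(df[[col]])
    if ("arm" %in% names(df)) {
        if (anyNA(df$arm)) stop("arm must be non-missing for every sample")
        df$arm <- stats::relevel(df$arm, ref = "control")
    }
    rownames(df) <- df$sample_id
    df
}

#' @rdname readCovariates
#' @param covariates data.frame to write.
#' @export
writeCovariates <- function(covariates, path) {
    utils::write.table(covariates, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read / write probe annotation
#'
#' TSV columns: probe_id, chrom, pos (1-based), gene, and optional logical
#' flag columns sex_chromosome / ambiguous_mapping / snp_in_probe.
#' @param path TSV path.
#' @export
readAnnotation <- function(path) {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
}

#' @rdname readAnnotation
#' @param annotation data.frame to write.
#' @export
writeAnnotation <- function(annotation, path) {
    utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read genotypes from VCF or dosage TSV
#'
#' The VCF dialect is minimal: diploid GT calls (\code{0/0}, \code{0/1},
#' \code{1/1}, phased or unphased), \code{./.} for missing; multiallelic
#' records and non-diploid calls are rejected. The TSV dialect has columns
#' snp_id, chrom, pos, ref, alt followed by one integer column per sample.
#'
#' @param path file path; treated as VCF when it ends in \code{.vcf}.
#' @param format "auto", "vcf" or "tsv".
#' @return A \linkS4class{GenotypeExperiment} of alt-allele dosages.
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "tsv")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
    if (format == "vcf") .read_genotypes_vcf(path) else
        .read_genotypes_tsv(path)
}

.read_genotypes_vcf <- function(path) {
    vcf <- VariantAnnotation::readVcf(path)
    alt <- VariantAnnotation::alt(vcf)
    if (any(S4Vectors::elementNROWS(alt) > 1L))
        stop("multiallelic records are not supported")
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt)) stop("VCF has no GT field")
    gt <- gsub("|", "/", gt, fixed = TRUE)
    known <- c("0/0", "0/1", "1/0", "1/1", "./.")
    if (!all(gt %in% known))
        stop("unsupported genotype call(s): ",
             paste(unique(gt[!gt %in% known]), collapse = ", "),
             " (diploid biallelic calls required)")
    dos <- matrix(NA_integer_, nrow(gt), ncol(gt),
                  dimnames = dimnames(gt))
    dos[gt == "0/0"] <- 0L
    dos[gt %in% c("0/1", "1/0")] <- 1L
    dos[gt == "1/1"] <- 2L
    rr <- SummarizedExperiment::rowRanges(vcf)
    snp_info <- data.frame(
        snp_id = rownames(gt),
        chrom = as.character(seqnames(rr)),
        pos = start(rr),
        ref = as.character(VariantAnnotation::ref(vcf)),
        alt = as.character(unlist(alt)))
    GenotypeExperiment(dos, snp_info)
}

.read_genotypes_tsv <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    meta <- c("snp_id", "chrom", "pos", "ref", "alt")
    if (!all(meta %in% names(df)))
        stop("dosage TSV needs columns: ", paste(meta, collapse = ", "))
    m <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
    storage.mode(m) <- "integer"
    if (!all(m %in% c(0L, 1L, 2L, NA)))
        stop("dosages must be 0, 1, 2 or NA")
    rownames(m) <- df$snp_id
    GenotypeExperiment(m, df[meta])
}

#' Write genotypes as dosage TSV or minimal VCF
#' @param ge a \code{GenotypeExperiment}.
#' @param path output path.
#' @export
writeGenotypesTsv <- function(ge, path) {
    gr <- rowRanges(ge)
    df <- data.frame(snp_id = names(gr),
                     chrom = as.character(seqnames(gr)), pos = start(gr),
                     ref = gr$ref, alt = gr$alt, check.names = FALSE)
    df <- cbind(df, as.data.frame(dosages(ge), check.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeGenotypesTsv
#' @export
writeGenotypesVcf <- function(ge, path) {
    gr <- rowRanges(ge)
    d <- dosages(ge)
    gt <- matrix("./.", nrow(d), ncol(d))
    gt[!is.na(d) & d == 0L] <- "0/0"
    gt[!is.na(d) & d == 1L] <- "0/1"
    gt[!is.na(d) & d == 2L] <- "1/1"
    hdr <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(d)), collapse = "\t"))
    body <- paste(as.character(seqnames(gr)), start(gr), names(gr), gr$ref,
                  gr$alt, ".", ".", ".", "GT",
                  apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Read a CpG set (one probe id per line)
#' @param path text file path.
#' @param name set name (defaults to the file name).
#' @return list with \code{name}, \code{probe_ids}, \code{size}.
#' @export
readCpGSet <- function(path, name = NULL) {
    ids <- unique(readLines(path))
    ids <- ids[nzchar(ids)]
    cpgSet(if (is.null(name)) basename(path) else name, ids)
}

#' Construct a named CpG set
#' @param name set name.
#' @param probe_ids character vector of probe ids (deduplicated).
#' @export
cpgSet <- function(name, probe_ids) {
    probe_ids <- unique(as.character(probe_ids))
    structure(list(name = name, probe_ids = probe_ids,
                   size = length(probe_ids)), class = "CpGSet")
}

#' @export
print.CpGSet <- function(x, ...) {
    cat(sprintf("CpGSet '%s': %d probes\n", x$name, x$size))
    invisible(x)
}

#' Export regions as BED (0-based half-open)
#' @param regions a GRanges of regions (as returned by the region callers).
#' @param path output path.
#' @export
writeRegionsBed <- function(regions, path) {
    df <- data.frame(chrom = as.character(seqnames(regions)),
                     start = start(regions) - 1L, end = end(regions),
                     name = if (!is.null(names(regions))) names(regions) else
                         sprintf("region_%d", seq_along(regions)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write a results table to TSV at full double precision
#' @param df data.frame.
#' @param path output path.
#' @export
writeResultsTsv <- function(df, path) {
    df2 <- df
    num <- vapply(df2, is.numeric, logical(1))
    df2[num] <- lapply(df2[num], function(x) sprintf("%.17g", x))
    df2[num] <- lapply(df2[num], function(x) ifelse(x == "NA", "NA", x))
    utils::write.table(df2, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
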