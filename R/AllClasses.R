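#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end findOverlaps resize
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#'   colData rowData assayNames
NULL

.BETA_TOL <- 1e-9

#' Container for array methylation beta values
#'
#' Extends \linkS4class{RangedSummarizedExperiment}. The \code{"beta"} assay
#' holds methylation fractions in \eqn{[0,1]} (probes x samples); optional
#' \code{"detection_p"} and \code{"bead_count"} assays carry per-cell QC
#' signals. Probe annotation (position, gene, QC flags) lives in
#' \code{rowRanges}, per-sample covariates in \code{colData}.
#'
#' @export
setClass("MethylationExperiment", contains = "RangedSummarizedExperiment")

setValidity("MethylationExperiment", function(object) {
    if (!"beta" %in% assayNames(object))
        return("assay 'beta' is required")
    b <- assay(object, "beta")
    bad <- !is.na(b) & (b < -.BETA_TOL | b > 1 + .BETA_TOL)
    if (any(bad)) {
        i <- which(bad, arr.ind = TRUE)[1L, ]
        return(sprintf("beta outside [0,1]: probe '%s', sample '%s' (%g)",
                       rownames(b)[i[1L]], colnames(b)[i[2L]], b[i[1L], i[2L]]))
    }
    if (anyDuplicated(rownames(object)))
        return("duplicate probe ids")
    TRUE
})

#' Container for additive allelic dosages
#'
#' Extends \linkS4class{RangedSummarizedExperiment}. The \code{"dosage"}
#' assay holds alt-allele counts per sample (0/1/2, \code{NA} allowed);
#' SNP metadata (ref/alt alleles) lives in \code{rowRanges}.
#'
#' @export
setClass("GenotypeExperiment", contains = "RangedSummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
    if (!"dosage" %in% assayNames(object))
        return("assay 'dosage' is required")
    d <- assay(object, "dosage")
    if (!all(d %in% c(0L, 1L, 2L, NA)))
        return("dosages must be 0, 1, 2 or NA")
    if (anyDuplicated(rownames(object)))
        return("duplicate snp ids")
    TRUE
})

.probe_granges <- function(annotation) {
    stopifnot(all(c("probe_id", "chrom", "pos") %in% names(annotation)))
    if (anyDuplicated(annotation$probe_id))
        stop("duplicate probe ids in annotation")
    if (any(annotation$pos < 1L))
        stop("probe positions must be >= 1 (1-based manifest convention)")
    gr <- GRanges(annotation$chrom, IRanges(annotation$pos, width = 1L))
    names(gr) <- annotation$probe_id
    gr$gene <- if (is.null(annotation$gene)) NA_character_ else
        as.character(annotation$gene)
    for (fl in c("sex_chromosome", "ambiguous_mapping", "snp_in_probe")) {
        v <- annotation[[fl]]
        S4Vectors::mcols(gr)[[fl]] <- if (is.null(v)) rep(FALSE, length(gr))
            else as.logical(v)
    }
    gr
}

#' Construct a MethylationExperiment
#'
#' @param betas numeric matrix, probes x samples, values in \eqn{[0,1]} or NA.
#' @param annotation data.frame with columns \code{probe_id}, \code{chrom},
#'   \code{pos} (1-based), optional \code{gene} and logical flag columns
#'   \code{sex_chromosome}, \code{ambiguous_mapping}, \code{snp_in_probe}.
#'   May also be a \code{GRanges} with matching names.
#' @param covariates data.frame of per-sample covariates with a
#'   \code{sample_id} column (or rownames) matching \code{colnames(betas)}.
#' @param detection_p,bead_count optional matrices of the same shape as
#'   \code{betas}.
#' @return A \linkS4class{MethylationExperiment}.
#' @export
MethylationExperiment <- function(betas, annotation = NULL, covariates = NULL,
                                  detection_p = NULL, bead_count = NULL) {
    betas <- as.matrix(betas)
    if (is.null(annotation)) {
        annotation <- data.frame(probe_id = rownames(betas), chrom = "un",
                                 pos = seq_len(nrow(betas)))
    }
    gr <- if (is(annotation, "GRanges")) annotation else
        .probe_granges(annotation)
    if (!setequal(rownames(betas), names(gr)))
        stop("annotation does not cover the probes of the beta matrix")
    gr <- gr[rownames(betas)]
    cd <- if (is.null(covariates)) {
        DataFrame(row.names = colnames(betas))
    } else {
        covariates <- as.data.frame(covariates)
        if ("sample_id" %in% names(covariates))
            rownames(covariates) <- covariates$sample_id
        if (!setequal(colnames(betas), rownames(covariates)))
            stop("covariate table does not match the samples of the matrix")
        DataFrame(covariates[colnames(betas), , drop = FALSE])
    }
    al <- list(beta = betas)
    if (!is.null(detection_p)) al$detection_p <- as.matrix(detection_p)
    if (!is.null(bead_count)) al$bead_count <- as.matrix(bead_count)
    se <- SummarizedExperiment(assays = al, rowRanges = gr, colData = cd)
    new("MethylationExperiment", se)
}

#' Construct a GenotypeExperiment
#'
#' @param dosages integer matrix of alt-allele dosages, SNPs x samples,
#'   values 0/1/2 or NA.
#' @param snp_info data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}.
#' @return A \linkS4class{GenotypeExperiment}.
#' @export
GenotypeExperiment <- function(dosages, snp_info) {
    dosages <- as.matrix(dosages)
    storage.mode(dosages) <- "integer"
    stopifnot(all(c("snp_id", "chrom", "pos", "ref", "alt") %in%
                  names(snp_info)))
    if (anyDuplicated(snp_info$snp_id)) stop("duplicate snp ids")
    gr <- GRanges(snp_info$chrom, IRanges(snp_info$pos, width = 1L),
                  ref = as.character(snp_info$ref),
                  alt = as.character(snp_info$alt))
    names(gr) <- snp_info$snp_id
    if (is.null(rownames(dosages))) rownames(dosages) <- names(gr)
    gr <- gr[rownames(dosages)]
    se <- SummarizedExperiment(assays = list(dosage = dosages),
                               rowRanges = gr)
    new("GenotypeExperiment", se)
}

#' @describeIn MethylationExperiment beta-value matrix accessor
#' @param object,x a \code{MethylationExperiment}
#' @export
setGeneric("betas", function(object) standardGeneric("betas"))

#' @rdname MethylationExperiment
#' @export
setMethod("betas", "MethylationExperiment",
          function(object) assay(object, "beta"))

#' @describeIn GenotypeExperiment dosage matrix accessor
#' @export
setGeneric("dosages", function(object) standardGeneric("dosages"))

#' @rdname GenotypeExperiment
#' @export
setMethod("dosages", "GenotypeExperiment",
          function(object) assay(object, "dosage"))

#' Per-sample covariates as a data.frame
#' @param object a \code{MethylationExperiment}
#' @export
setGeneric("covariates", function(object) standardGeneric("covariates"))

#' @rdname covariates
#' @export
setMethod("covariates", "MethylationExperiment",
          function(object) as.data.frame(colData(object)))

#' Probe annotation as a data.frame (probe_id, chrom, pos, gene, flags)
#' @param object a \code{MethylationExperiment}
#' @export
setGeneric("probeAnnotation", function(object) standardGeneric("probeAnnotation"))

#' @rdname probeAnnotation
#' @export
setMethod("probeAnnotation", "MethylationExperiment", function(object) {
    gr <- rowRanges(object)
    df <- data.frame(probe_id = names(gr),
                     chrom = as.character(seqnames(gr)),
                     pos = start(gr))
    cbind(df, as.data.frame(S4Vectors::mcols(gr)))
})

setMethod("show", "MethylationExperiment", function(object) {
    cat(sprintf("MethylationExperiment: %d probes x %d samples\n",
                nrow(object), ncol(object)))
    cat("assays:", paste(assayNames(object), collapse = ", "), "\n")
    if ("arm" %in% colnames(colData(object))) {
        tb <- table(colData(object)$arm)
        cat("arms:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
            "\n")
    }
    cat("covariates:", paste(colnames(colData(object)), collapse = ", "), "\n")
})

setMethod("show", "GenotypeExperiment", function(object) {
    d <- dosages(object)
    cat(sprintf("GenotypeExperiment: %d SNPs x %d samples (%.2f%% missing)\n",
                nrow(object), ncol(object), 100 * mean(is.na(d))))
})
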