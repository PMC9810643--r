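## Readers/writers for the standard formats the pipeline touches.
## Internal containers are GRanges (1-based closed); BED, fragment tables
## and the SV table are 0-based half-open on disk, VCF is 1-based.
## Conversions happen only here, at the format boundary.

.FRAG_HEADER <- c("chrom", "start", "end", "cell", "mapq", "read_id",
                  "cigar", "anchors", "species")

#' Read long-read scATAC fragments
#'
#' Reads per-cell long-read fragments either from a BAM/SAM file carrying a
#' cell-identity tag or from a plain-text fragment table
#' (tab-separated, 0-based half-open coordinates, columns
#' \code{chrom start end cell mapq [read_id cigar anchors species]}; an
#' optional header line starting with \code{#}). Secondary alignments are
#' dropped; supplementary alignments are attached to their primary record as
#' split-alignment anchors.
#'
#' @param path Path to a \code{.bam}/\code{.sam} file or a fragment table.
#' @param minMapq Minimum mapping quality; records below are dropped
#'   (default 30, a typical threshold for variant-bearing long reads).
#' @param cellTag BAM tag holding the cell identity (default \code{"CB"};
#'   \code{"RG"} uses the read group).
#' @return An \code{\link{ScFragments}} object. The number of skipped
#'   malformed records is available as
#'   \code{metadata(x)$n_skipped}.
#' @export
readFragments <- function(path, minMapq = 30L, cellTag = "CB") {
    if (!file.exists(path)) stop("cannot read fragment input: ", path)
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("bam", "sam"))
        .readFragmentsBam(path, minMapq, cellTag)
    else
        .readFragmentsTable(path, minMapq)
}

.readFragmentsTable <- function(path, minMapq) {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            data.table = TRUE, fill = TRUE)
    if (nrow(dt) && startsWith(as.character(dt[[1L]][1L]), "#"))
        dt <- dt[-1L]
    if (ncol(dt) < 5L)
        stop("fragment table needs >= 5 columns (chrom start end cell mapq)")
    names(dt)[seq_len(min(ncol(dt), 9L))] <-
        .FRAG_HEADER[seq_len(min(ncol(dt), 9L))]
    start0 <- suppressWarnings(as.numeric(dt$start))
    end0 <- suppressWarnings(as.numeric(dt$end))
    bad <- is.na(start0) | is.na(end0) | start0 >= end0
    nbad <- sum(bad)
    if (nbad)
        warning(nbad, " record(s) with start >= end or unparsable ",
                "coordinates skipped")
    keep <- !bad & as.integer(dt$mapq) >= minMapq
    dt <- dt[keep]
    opt <- function(col, default) {
        if (!is.null(dt[[col]])) {
            v <- as.character(dt[[col]])
            v[v == "." | is.na(v)] <- default
            v
        } else rep(default, nrow(dt))
    }
    gr <- GRanges(dt$chrom,
                  IRanges(start = start0[keep] + 1L, end = end0[keep]),
                  cell = as.character(dt$cell),
                  mapq = as.integer(dt$mapq),
                  read_id = opt("read_id", NA_character_),
                  cigar = opt("cigar", ""),
                  anchors = opt("anchors", ""),
                  species = opt("species", NA_character_))
    if (anyNA(mcols(gr)$read_id))
        mcols(gr)$read_id <- sprintf("frag%08d", seq_along(gr))
    out <- ScFragments(gr)
    metadata(out)$n_skipped <- nbad
    out
}

.readFragmentsBam <- function(path, minMapq, cellTag) {
    if (tolower(tools::file_ext(path)) == "sam") {
        dest <- tempfile(fileext = "")
        path <- Rsamtools::asBam(path, destination = dest,
                                 overwrite = TRUE, indexDestination = FALSE)
    }
    what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "strand")
    p <- Rsamtools::ScanBamParam(what = what, tag = cellTag)
    res <- Rsamtools::scanBam(path, param = p)[[1L]]
    tagval <- res[["tag"]][[cellTag]]
    if (is.null(tagval)) tagval <- rep(NA_character_, length(res$qname))
    flag <- res$flag
    unmapped <- bitwAnd(flag, 4L) > 0L
    secondary <- bitwAnd(flag, 256L) > 0L
    suppl <- bitwAnd(flag, 2048L) > 0L
    refwidth <- rep(NA_integer_, length(flag))
    ok <- !unmapped & !is.na(res$cigar)
    refwidth[ok] <-
        GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar[ok])
    primary <- ok & !secondary & !suppl & res$mapq >= minMapq
    ## supplementary records become split anchors on their primary
    anchors <- rep("", sum(primary))
    if (any(suppl & ok)) {
        sup <- paste0(as.character(res$rname)[suppl & ok], ":",
                      res$pos[suppl & ok], ":",
                      as.character(res$strand)[suppl & ok])
        supByQ <- split(sup, res$qname[suppl & ok])
        idx <- match(res$qname[primary], names(supByQ))
        hit <- !is.na(idx)
        anchors[hit] <- vapply(supByQ[idx[hit]], paste, "", collapse = ";")
    }
    gr <- GRanges(as.character(res$rname)[primary],
                  IRanges(start = res$pos[primary],
                          width = refwidth[primary]),
                  cell = as.character(tagval)[primary],
                  mapq = as.integer(res$mapq)[primary],
                  read_id = res$qname[primary],
                  cigar = res$cigar[primary],
                  anchors = anchors,
                  species = NA_character_)
    out <- ScFragments(gr)
    metadata(out)$n_skipped <- 0L
    out
}

#' Write a fragment table
#'
#' Writes the 9-column tab-separated fragment table (0-based half-open),
#' with a \code{#}-prefixed header line. \code{readFragments} /
#' \code{writeFragments} round-trip is the identity.
#'
#' @param frags \code{\link{ScFragments}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeFragments <- function(frags, path) {
    mc <- mcols(frags)
    dot <- function(v) { v <- as.character(v); v[!nzchar(v) | is.na(v)] <- "."; v }
    dt <- data.table::data.table(
        chrom = as.character(seqnames(frags)),
        start = start(frags) - 1L, end = end(frags),
        cell = mc$cell, mapq = mc$mapq, read_id = mc$read_id,
        cigar = dot(mc$cigar), anchors = dot(mc$anchors),
        species = dot(mc$species))
    writeLines(paste0("#", paste(.FRAG_HEADER, collapse = "\t")), path)
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE,
                       append = TRUE)
    invisible(path)
}

#' Tn5 insertion ends of fragments
#'
#' Each fragment yields exactly two single-bp insertion ends. In 0-based
#' terms the left end sits at \code{start + shiftPlus} and the right end at
#' \code{end - 1 - shiftMinus}; the defaults are the standard ATAC +4/-5
#' Tn5 offset correction. Ends are clipped to the fragment (and chromosome
#' bounds when \code{seqlengths} are set) and ordered so left <= right even
#' for degenerate, very short fragments.
#'
#' @param frags \code{\link{ScFragments}} (or a GRanges with \code{cell} and
#'   \code{read_id} columns).
#' @param shiftPlus,shiftMinus Tn5 offsets applied to the left/right end.
#' @return A \code{GRanges} of width-1 insertion ends with metadata columns
#'   \code{cell}, \code{read_id} and \code{side} (\code{"left"} or
#'   \code{"right"}); length is exactly \code{2 * length(frags)}.
#' @export
fragmentEnds <- function(frags, shiftPlus = 4L, shiftMinus = 5L) {
    s <- start(frags); e <- end(frags)
    left <- pmin(pmax(s + shiftPlus, s), e)
    right <- pmin(pmax(e - shiftMinus, s), e)
    lo <- pmin(left, right); hi <- pmax(left, right)
    chr <- as.character(seqnames(frags))
    sl <- seqlengths(frags)
    if (!all(is.na(sl))) {
        lim <- sl[chr]
        hasLim <- !is.na(lim)
        lo[hasLim] <- pmin(pmax(lo[hasLim], 1L), lim[hasLim])
        hi[hasLim] <- pmin(pmax(hi[hasLim], 1L), lim[hasLim])
    }
    gr <- GRanges(rep(chr, 2L),
                  IRanges(start = c(lo, hi), width = 1L),
                  cell = rep(mcols(frags)$cell, 2L),
                  read_id = rep(mcols(frags)$read_id, 2L),
                  side = rep(c("left", "right"), each = length(frags)))
    seqlengths(gr) <- sl[seqlevels(gr)]
    gr
}

#' Read and write peak BED files
#'
#' BED is 0-based half-open on disk; in memory peaks are 1-based closed
#' \code{GRanges}. BED3/BED5 round-trips are byte-identical.
#'
#' @param path BED path.
#' @return \code{readPeakBed}: a \code{GRanges}, with \code{name} and
#'   \code{score} columns when present in the file.
#' @export
readPeakBed <- function(path) {
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e)
                       stop("malformed BED '", path, "': ",
                            conditionMessage(e)))
    gr
}

#' @rdname readPeakBed
#' @param peaks \code{GRanges} of peaks.
#' @export
writePeakBed <- function(peaks, path) {
    dt <- data.table::data.table(chrom = as.character(seqnames(peaks)),
                                 start = start(peaks) - 1L,
                                 end = end(peaks))
    nm <- mcols(peaks)$name; sc <- mcols(peaks)$score
    if (!is.null(nm) || !is.null(sc)) {
        dt$name <- if (is.null(nm)) "." else nm
        if (!is.null(sc)) dt$score <- sc
    }
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
    invisible(path)
}

#' Read heterozygous SNVs from a VCF
#'
#' Keeps biallelic single-nucleotide variants with a heterozygous genotype
#' in the first sample. A phased genotype \code{a|b} assigns
#' \code{hap1}/\code{hap2} alleles (hap1 first); an unphased \code{a/b}
#' leaves the variant unphased. Positions stay 1-based, matching the VCF.
#'
#' @param path VCF path (plain text or bgzipped).
#' @return data.frame with columns \code{chrom, pos, ref, alt, hap1, hap2,
#'   phased, phase_set}.
#' @export
readVcfHets <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    gt <- vcfR::extract.gt(v, element = "GT")[, 1L]
    ps <- tryCatch(suppressWarnings(
        vcfR::extract.gt(v, element = "PS")[, 1L]),
        error = function(e) rep(NA_character_, length(gt)))
    ref <- fix[, "REF"]; alt <- fix[, "ALT"]
    snv <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt)
    phased <- grepl("|", gt, fixed = TRUE)
    a1 <- as.integer(sub("[|/].*", "", gt))
    a2 <- as.integer(sub(".*[|/]", "", gt))
    het <- !is.na(a1) & !is.na(a2) & a1 != a2 & a1 <= 1L & a2 <= 1L
    keep <- snv & het
    pick <- function(idx, i) ifelse(idx == 0L, ref[i], alt[i])
    i <- which(keep)
    data.frame(chrom = fix[i, "CHROM"],
               pos = as.integer(fix[i, "POS"]),
               ref = ref[i], alt = alt[i],
               hap1 = ifelse(phased[i], pick(a1[i], i), NA_character_),
               hap2 = ifelse(phased[i], pick(a2[i], i), NA_character_),
               phased = phased[i],
               phase_set = ifelse(is.na(ps[i]), ".", ps[i]),
               row.names = NULL)
}

#' Write heterozygous SNVs as a VCF
#'
#' Emits a minimal single-sample VCFv4.2 with \code{GT} (and \code{PS} for
#' phased variants): phased variants as \code{0|1}/\code{1|0} according to
#' their hap1 allele, unphased ones as \code{0/1}.
#'
#' @param variants data.frame as returned by \code{\link{readVcfHets}}.
#' @param path Output path.
#' @param sample Sample name in the header.
#' @export
writeVcfHets <- function(variants, path, sample = "sample1") {
    hdr <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste0("##FORMAT=<ID=PS,Number=1,Type=Integer,",
                    "Description=\"Phase set\">"),
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample, sep = "\t"))
    gt <- ifelse(!variants$phased, "0/1",
                 ifelse(variants$hap1 == variants$ref, "0|1", "1|0"))
    ps <- as.character(variants$phase_set)
    hasPs <- variants$phased & !is.na(ps) & ps != "."
    fmt <- ifelse(hasPs, "GT:PS", "GT")
    val <- ifelse(hasPs, paste0(gt, ":", ps), gt)
    lines <- paste(variants$chrom, variants$pos, ".", variants$ref,
                   variants$alt, ".", "PASS", ".", fmt, val, sep = "\t")
    writeLines(c(hdr, lines), path)
    invisible(path)
}

#' Read and write per-read SNP allele observations
#'
#' The allele-observation table links reads to the heterozygous SNP alleles
#' they carry: columns \code{read_id, chrom, pos, allele}, with \code{pos}
#' 1-based (VCF convention). Produced by the simulator; for real data it is
#' extracted upstream from the alignments.
#'
#' @param path TSV path.
#' @return data.frame of observations.
#' @export
readAlleleObs <- function(path) {
    dt <- data.table::fread(path, header = TRUE, sep = "\t")
    as.data.frame(dt)
}

#' @rdname readAlleleObs
#' @param obs data.frame of observations.
#' @export
writeAlleleObs <- function(obs, path) {
    data.table::fwrite(obs, path, sep = "\t")
    invisible(path)
}

#' Read and write the SV result table
#'
#' Tab-separated with header
#' \code{type chrom pos length chrom2 pos2 n_cells n_reads cells};
#' \code{pos}/\code{pos2} are 0-based on disk, 1-based in memory.
#'
#' @param calls data.frame of SV calls (as returned by
#'   \code{\link{callSvs}}).
#' @param path Output path.
#' @export
writeSvTable <- function(calls, path) {
    out <- data.frame(type = calls$type, chrom = calls$chrom,
                      pos = calls$pos - 1L, length = calls$length,
                      chrom2 = ifelse(is.na(calls$chrom2), ".",
                                      calls$chrom2),
                      pos2 = ifelse(is.na(calls$pos2), ".",
                                    as.character(calls$pos2 - 1L)),
                      n_cells = calls$n_cells, n_reads = calls$n_reads,
                      cells = calls$cells)
    data.table::fwrite(out, path, sep = "\t")
    invisible(path)
}

#' @rdname writeSvTable
#' @export
readSvTable <- function(path) {
    dt <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t",
                                          colClasses = list(
                                              character = c("chrom2",
                                                            "pos2"))))
    dt$pos <- as.integer(dt$pos) + 1L
    dt$chrom2 <- ifelse(dt$chrom2 == ".", NA_character_, dt$chrom2)
    dt$pos2 <- ifelse(dt$pos2 == ".", NA_integer_,
                      suppressWarnings(as.integer(dt$pos2)) + 1L)
    dt
}

#' Percentage reporting helper
#'
#' Formats a count over a total as a percentage at the stated precision;
#' used by the summary reports (e.g. peak-overlap fractions, doublet
#' rates).
#'
#' @param n Numerator count.
#' @param total Denominator count.
#' @param digits Decimal digits (default 1).
#' @return Numeric percentage.
#' @export
percentOf <- function(n, total, digits = 1) round(100 * n / total, digits)
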