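#' Write variant calls as VCF 4.2
#'
#' SNVs and small indels with known sequence are written with explicit
#' REF/ALT alleles; SVs use symbolic ALTs (`<DEL>`, `<DUP>`, `<INS>`,
#' `<INV>`) with `END` and `SVLEN`; translocations are written as paired
#' breakend (BND) records cross-referenced by `MATEID` and annotated with
#' `CHR2`/`POS2`. Internally coordinates are 0-based half-open; VCF output
#' uses the conventional 1-based anchor-base representation.
#'
#' @param calls data.frame with columns `chrom`, `pos` (0-based), `end`
#'   (0-based exclusive; NA where not applicable), `type` (SNV, INS, DEL,
#'   DUP, INV, TRA), `len`, `ref`, `alt` (sequences, NA when unknown),
#'   `support`, `p_bc`, `gt`, `mate_chrom`, `mate_pos`.
#' @param path output file.
#' @param contigs named vector of contig lengths.
#' @param genome optional named list of chromosome sequences (character);
#'   needed to emit explicit alleles for deletions.
#' @param sample sample name for the single genotype column.
#' @return the path, invisibly.
#' @export
write_vcf <- function(calls, path, contigs, genome = NULL,
                      sample = "SAMPLE") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=omnivar",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs),
            as.integer(contigs)),
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of structural variant\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Float,Description=\"Weighted supporting read count\">",
    "##INFO=<ID=PBC,Number=1,Type=Float,Description=\"Binomial mismapping probability\">",
    "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Partner chromosome of a breakend\">",
    "##INFO=<ID=POS2,Number=1,Type=Integer,Description=\"Partner position of a breakend (1-based)\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"ID of the mate breakend\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Breakpoints not base-resolved\">",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  if (is.null(calls) || nrow(calls) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  for (col in c("ref", "alt", "gt", "mate_chrom")) {
    if (is.null(calls[[col]])) calls[[col]] <- NA_character_
  }
  for (col in c("end", "len", "support", "p_bc", "mate_pos")) {
    if (is.null(calls[[col]])) calls[[col]] <- NA_real_
  }
  for (col in c("pos", "end", "len", "mate_pos")) {   # no scientific notation
    calls[[col]] <- as.integer(round(calls[[col]]))
  }
  qual <- ifelse(is.na(calls$p_bc), ".",
                 sprintf("%.6g", pmin(-10 * log10(pmax(calls$p_bc, 1e-300)),
                                      3000)))
  anchor <- function(chrom, p0) {
    # base at 0-based position p0 - 1 (the VCF anchor base)
    if (is.null(genome)) return(rep("N", length(p0)))
    mapply(function(ch, p) substr(genome[[ch]], p, p), chrom, p0,
           USE.NAMES = FALSE)
  }
  lines <- character(0)
  ids <- sprintf("var%05d", seq_len(nrow(calls)))
  for (i in seq_len(nrow(calls))) {
    x <- calls[i, ]
    info <- c(
      if (!is.na(x$support)) sprintf("SUPPORT=%.6g", x$support),
      if (!is.na(x$p_bc)) sprintf("PBC=%.6g", x$p_bc))
    gt <- if (is.na(x$gt)) "./." else x$gt
    if (x$type == "SNV") {
      lines <- c(lines, paste(x$chrom, x$pos + 1, ids[i], x$ref, x$alt,
                              qual[i], "PASS",
                              if (length(info)) paste(info, collapse = ";") else ".",
                              "GT", gt, sep = "\t"))
    } else if (x$type == "TRA") {
      id1 <- paste0(ids[i], "_bnd1"); id2 <- paste0(ids[i], "_bnd2")
      i1 <- paste(c(info, "SVTYPE=BND",
                    sprintf("CHR2=%s;POS2=%d;MATEID=%s", x$mate_chrom,
                            as.integer(x$mate_pos + 1), id2)), collapse = ";")
      i2 <- paste(c(info, "SVTYPE=BND",
                    sprintf("CHR2=%s;POS2=%d;MATEID=%s", x$chrom,
                            as.integer(x$pos + 1), id1)), collapse = ";")
      lines <- c(lines,
        paste(x$chrom, x$pos, id1, "N",
              sprintf("N[%s:%d[", x$mate_chrom, as.integer(x$mate_pos + 1)),
              qual[i], "PASS", i1, "GT", gt, sep = "\t"),
        paste(x$mate_chrom, x$mate_pos, id2, "N",
              sprintf("]%s:%d]N", x$chrom, as.integer(x$pos)),
              qual[i], "PASS", i2, "GT", gt, sep = "\t"))
    } else if (x$type == "DEL" && x$len < 50 && !is.null(genome)) {
      ref <- substr(genome[[x$chrom]], x$pos, x$pos + x$len)  # anchor + deleted
      lines <- c(lines, paste(x$chrom, x$pos, ids[i], ref, substr(ref, 1, 1),
                              qual[i], "PASS",
                              if (length(info)) paste(info, collapse = ";") else ".",
                              "GT", gt, sep = "\t"))
    } else if (x$type == "INS" && !is.na(x$alt)) {
      a <- anchor(x$chrom, x$pos)
      lines <- c(lines, paste(x$chrom, x$pos, ids[i], a,
                              paste0(a, x$alt), qual[i], "PASS",
                              if (length(info)) paste(info, collapse = ";") else ".",
                              "GT", gt, sep = "\t"))
    } else {
      svlen <- if (x$type == "DEL") -x$len else x$len
      info2 <- paste(c(info, sprintf("SVTYPE=%s", x$type),
                       if (!is.na(x$end)) sprintf("END=%d", as.integer(x$end)),
                       if (!is.na(svlen)) sprintf("SVLEN=%d", as.integer(svlen)),
                       if (x$type == "INS" && is.na(x$len)) "IMPRECISE"),
                     collapse = ";")
      lines <- c(lines, paste(x$chrom, x$pos, ids[i], "N",
                              sprintf("<%s>", x$type), qual[i], "PASS",
                              info2, "GT", gt, sep = "\t"))
    }
  }
  # sort body by contig order then position
  ch <- sub("\t.*", "", lines)
  p <- as.integer(sub("^[^\t]*\t([0-9]+)\t.*", "\\1", lines))
  lines <- lines[order(match(ch, names(contigs)), p)]
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write a simulator truth set as VCF
#' @param variants simulator variant data.frame (0-based `pos`).
#' @param genome named list of chromosome sequences.
#' @param contigs named vector of contig lengths.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_truth_vcf <- function(variants, genome, contigs, path) {
  v <- variants
  n <- nrow(v)
  if (n == 0) {
    return(write_vcf(NULL, path, contigs, genome = genome,
                     sample = "TRUTH"))
  }
  calls <- data.frame(
    chrom = v$chrom, pos = v$pos, type = v$type,
    len = ifelse(v$type == "SNV", 1,
                 ifelse(v$type == "INS", nchar(as.character(v$alt)), v$len)),
    end = ifelse(v$type %in% c("DEL", "DUP", "INV"), v$pos + v$len, NA),
    ref = rep(NA_character_, n), alt = as.character(v$alt),
    support = NA_real_, p_bc = NA_real_,
    gt = ifelse(v$zygosity == "hom", "1/1", "0/1"),
    mate_chrom = as.character(v$chrom2), mate_pos = v$pos2,
    stringsAsFactors = FALSE)
  if (any(v$type == "SNV")) {
    i <- which(v$type == "SNV")
    calls$ref[i] <- mapply(function(ch, p) substr(genome[[ch]], p + 1, p + 1),
                           v$chrom[i], v$pos[i], USE.NAMES = FALSE)
  }
  calls$type[calls$type == "TRA"] <- "TRA"
  write_vcf(calls, path, contigs, genome = genome, sample = "TRUTH")
}

#' Read a VCF of calls into the internal representation
#'
#' Understands the records this package writes (and simple third-party
#' equivalents): explicit SNV/indel alleles, symbolic SV ALTs with
#' `END`/`SVLEN`, and BND pairs with `CHR2`/`POS2`/`MATEID` (each pair is
#' collapsed to one TRA row).
#'
#' @param path VCF file.
#' @return data.frame with 0-based `chrom`, `pos`, `end`, `type`, `len`,
#'   `ref`, `alt`, `gt`, `mate_chrom`, `mate_pos`, `support`, `p_bc`.
#' @export
read_calls_vcf <- function(path) {
  ln <- readLines(path)
  body <- ln[!startsWith(ln, "#")]
  empty <- data.frame(chrom = character(0), pos = numeric(0),
                      end = numeric(0), type = character(0), len = numeric(0),
                      ref = character(0), alt = character(0),
                      gt = character(0), mate_chrom = character(0),
                      mate_pos = numeric(0), support = numeric(0),
                      p_bc = numeric(0), stringsAsFactors = FALSE)
  if (length(body) == 0) return(empty)
  f <- strsplit(body, "\t", fixed = TRUE)
  getf <- function(i) vapply(f, `[`, character(1), i)
  chrom <- getf(1); pos1 <- as.numeric(getf(2)); id <- getf(3)
  ref <- getf(4); alt <- getf(5); info <- getf(8)
  gt <- if (all(lengths(f) >= 10)) sub(":.*", "", getf(10)) else NA
  ikey <- function(key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    out <- rep(NA_character_, length(info))
    hit <- grepl(paste0("(^|;)", key, "="), info)
    out[hit] <- sub(paste0(".*", key, "="), "", m)
    out
  }
  svtype <- ikey("SVTYPE")
  endi <- as.numeric(ikey("END"))
  svlen <- as.numeric(ikey("SVLEN"))
  chr2 <- ikey("CHR2"); pos2 <- as.numeric(ikey("POS2"))
  support <- as.numeric(ikey("SUPPORT")); pbc <- as.numeric(ikey("PBC"))

  out <- empty[rep(1L, 0), ]
  rows <- vector("list", length(body))
  for (i in seq_along(body)) {
    if (!is.na(svtype[i]) && svtype[i] == "BND") {
      # keep the first breakend of each mate pair
      if (grepl("_bnd2$", id[i])) next
      rows[[i]] <- data.frame(chrom = chrom[i], pos = pos1[i], end = NA_real_,
                              type = "TRA", len = NA_real_,
                              ref = NA_character_, alt = NA_character_,
                              gt = gt[i], mate_chrom = chr2[i],
                              mate_pos = pos2[i] - 1, support = support[i],
                              p_bc = pbc[i], stringsAsFactors = FALSE)
    } else if (startsWith(alt[i], "<")) {
      ty <- gsub("[<>]", "", alt[i])
      ln_i <- abs(svlen[i])
      rows[[i]] <- data.frame(chrom = chrom[i], pos = pos1[i],
                              end = endi[i], type = ty, len = ln_i,
                              ref = NA_character_, alt = NA_character_,
                              gt = gt[i], mate_chrom = NA_character_,
                              mate_pos = NA_real_, support = support[i],
                              p_bc = pbc[i], stringsAsFactors = FALSE)
    } else if (nchar(ref[i]) == 1 && nchar(alt[i]) == 1) {
      rows[[i]] <- data.frame(chrom = chrom[i], pos = pos1[i] - 1,
                              end = pos1[i], type = "SNV", len = 1,
                              ref = ref[i], alt = alt[i], gt = gt[i],
                              mate_chrom = NA_character_, mate_pos = NA_real_,
                              support = support[i], p_bc = pbc[i],
                              stringsAsFactors = FALSE)
    } else if (nchar(ref[i]) > nchar(alt[i])) {
      k <- nchar(ref[i]) - nchar(alt[i])
      rows[[i]] <- data.frame(chrom = chrom[i], pos = pos1[i],
                              end = pos1[i] + k, type = "DEL", len = k,
                              ref = ref[i], alt = alt[i], gt = gt[i],
                              mate_chrom = NA_character_, mate_pos = NA_real_,
                              support = support[i], p_bc = pbc[i],
                              stringsAsFactors = FALSE)
    } else {
      k <- nchar(alt[i]) - nchar(ref[i])
      rows[[i]] <- data.frame(chrom = chrom[i], pos = pos1[i],
                              end = pos1[i], type = "INS", len = k,
                              ref = ref[i], alt = substr(alt[i], 2, nchar(alt[i])),
                              gt = gt[i],
                              mate_chrom = NA_character_, mate_pos = NA_real_,
                              support = support[i], p_bc = pbc[i],
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) empty else out
}
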