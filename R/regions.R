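## Genome annotation container. Internal coordinates are 0-based half-open
## ([start, end)); GFF3 input (1-based inclusive) and GenBank locations are
## normalized on load.

new_genome_annotation <- function(chromosomes, features) {
  stopifnot(is.data.frame(chromosomes), is.data.frame(features))
  features <- features[order(features$chrom, features$start, features$end), ,
                       drop = FALSE]
  rownames(features) <- NULL
  structure(list(chromosomes = chromosomes, features = features),
            class = "genome_annotation")
}

#' Construct a genome annotation from a feature table
#'
#' @param chromosomes data.frame with columns `id`, `length` (bp).
#' @param features data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`), `type`
#'   (`gene`/`exon`/`CDS`), `gene_id` (parent gene identifier; for `gene`
#'   rows the gene's own identifier).
#' @return validated object of class `genome_annotation`.
#' @export
genome_annotation <- function(chromosomes, features) {
  ann <- new_genome_annotation(chromosomes, features)
  validate_annotation(ann)
  ann
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d chromosome(s), %s bp; %d genes, %d exons, %d CDS\n",
              nrow(x$chromosomes), format(sum(x$chromosomes$length), big.mark = ","),
              sum(x$features$type == "gene"), sum(x$features$type == "exon"),
              sum(x$features$type == "CDS")))
  invisible(x)
}

validate_annotation <- function(ann) {
  chr <- ann$chromosomes
  ft <- ann$features
  if (nrow(ft) == 0L) return(invisible(ann))
  missing_chr <- !(ft$chrom %in% chr$id)
  if (any(missing_chr)) {
    i <- which(missing_chr)[1]
    stop(sprintf("feature %s [%d,%d) references missing chromosome \"%s\"",
                 ft$type[i], ft$start[i], ft$end[i], ft$chrom[i]))
  }
  len <- chr$length[match(ft$chrom, chr$id)]
  bad <- ft$start < 0 | ft$start >= ft$end | ft$end > len
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("feature %s \"%s\" has invalid coordinates [%d,%d) on %s (length %d)",
                 ft$type[i], ft$gene_id[i], ft$start[i], ft$end[i], ft$chrom[i],
                 len[i]))
  }
  genes <- ft[ft$type == "gene", , drop = FALSE]
  sub <- ft[ft$type %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(sub) > 0L) {
    if (any(is.na(sub$gene_id) | sub$gene_id == ""))
      stop("every exon/CDS must name a parent gene")
    m <- match(sub$gene_id, genes$gene_id)
    if (anyNA(m)) {
      i <- which(is.na(m))[1]
      stop(sprintf("%s references unknown parent gene \"%s\"",
                   sub$type[i], sub$gene_id[i]))
    }
    outside <- sub$chrom != genes$chrom[m] | sub$start < genes$start[m] |
      sub$end > genes$end[m]
    if (any(outside)) {
      i <- which(outside)[1]
      stop(sprintf("%s [%d,%d) lies outside its parent gene \"%s\" [%d,%d)",
                   sub$type[i], sub$start[i], sub$end[i], sub$gene_id[i],
                   genes$start[m[i]], genes$end[m[i]]))
    }
  }
  invisible(ann)
}

#' Load a genome (FASTA) with its gene annotation (GFF3 or GenBank table)
#'
#' Sequences are upper-cased with non-ACGT letters preserved (they are
#' skipped window-wise during spectrum counting). Annotation coordinates
#' are normalized to the internal 0-based half-open convention. A feature
#' referencing a missing chromosome, or an exon/CDS outside its parent gene
#' span, is a hard error naming the offender.
#'
#' @param fasta_path multi-record FASTA file.
#' @param annotation_path GFF3 file or GenBank-style flat file.
#' @param format `"auto"` (by extension/first line), `"gff3"` or
#'   `"genbank"`.
#' @return object of class `genome`: list with `sequences`
#'   (`DNAStringSet`) and `annotation` (`genome_annotation`).
#' @export
load_genome <- function(fasta_path, annotation_path, format = "auto") {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  format <- match.arg(format, c("auto", "gff3", "genbank"))
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", annotation_path, ignore.case = TRUE))
      "gff3"
    else if (grepl("\\.(gb|gbk|gbff|genbank)$", annotation_path,
                   ignore.case = TRUE))
      "genbank"
    else if (startsWith(readLines(annotation_path, n = 1), "##gff"))
      "gff3"
    else "genbank"
  }
  chromosomes <- data.frame(id = names(seqs), length = Biostrings::width(seqs))
  features <- switch(format,
                     gff3 = parse_gff3_features(annotation_path),
                     genbank = parse_genbank_features(annotation_path))
  ann <- genome_annotation(chromosomes, features)
  structure(list(sequences = seqs, annotation = ann), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("genome object\n ")
  print(x$annotation)
  invisible(x)
}

## GFF3 -> internal feature frame; exon/CDS Parent chains (possibly via
## mRNA records) are resolved to the enclosing gene.
parse_gff3_features <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(md)) as.character(md$ID) else NA_character_
  parent <- if ("Parent" %in% names(md)) {
    vapply(as.list(md$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
  } else rep(NA_character_, length(gr))
  type <- as.character(md$type)
  parent_of <- stats::setNames(parent, id)
  type_of <- stats::setNames(type, id)
  resolve_gene <- function(p) {
    for (step in 1:10) {
      if (is.na(p)) return(NA_character_)
      if (!is.na(type_of[p]) && type_of[p] == "gene") return(unname(p))
      p <- unname(parent_of[p])
    }
    NA_character_
  }
  keep <- type %in% c("gene", "exon", "CDS")
  gr2 <- gr[keep]
  type2 <- type[keep]
  gene_id <- character(length(gr2))
  for (i in seq_along(gr2)) {
    gene_id[i] <- if (type2[i] == "gene") {
      if (is.na(id[keep][i])) sprintf("gene%04d", i) else id[keep][i]
    } else {
      resolve_gene(parent[keep][i])
    }
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr2)),
             start = GenomicRanges::start(gr2) - 1L,
             end = GenomicRanges::end(gr2),
             strand = ifelse(as.character(GenomicRanges::strand(gr2)) == "-",
                             "-", "+"),
             type = type2, gene_id = gene_id)
}

## Minimal GenBank flat-file feature-table reader: LOCUS records with
## gene/mRNA/CDS/exon features, join()/complement() locations, /gene= or
## /locus_tag= qualifiers as gene identifiers. Sequence data is ignored
## (the FASTA provides it).
parse_genbank_features <- function(path) {
  lines <- readLines(path)
  out <- list()
  locus <- NA_character_
  in_features <- FALSE
  cur <- NULL
  flush_feature <- function(cur) {
    if (is.null(cur)) return(NULL)
    loc <- parse_genbank_location(cur$location)
    gid <- cur$gene %||% cur$locus_tag %||% NA_character_
    data.frame(chrom = cur$locus, start = loc$start, end = loc$end,
               strand = if (loc$complement) "-" else "+",
               type = cur$key, gene_id = gid)
  }
  for (ln in lines) {
    if (startsWith(ln, "LOCUS")) {
      locus <- strsplit(trimws(sub("^LOCUS", "", ln)), "\\s+")[[1]][1]
      in_features <- FALSE
    } else if (startsWith(ln, "FEATURES")) {
      in_features <- TRUE
    } else if (startsWith(ln, "ORIGIN") || startsWith(ln, "//")) {
      out[[length(out) + 1L]] <- flush_feature(cur)
      cur <- NULL
      in_features <- FALSE
    } else if (in_features) {
      if (grepl("^ {5}\\S", ln)) {              # new feature key
        out[[length(out) + 1L]] <- flush_feature(cur)
        parts <- strsplit(trimws(ln), "\\s+")[[1]]
        key <- parts[1]
        if (key %in% c("gene", "exon", "CDS", "mRNA")) {
          cur <- list(key = key, locus = locus,
                      location = paste(parts[-1], collapse = ""))
        } else cur <- NULL
      } else if (!is.null(cur)) {
        txt <- trimws(ln)
        if (startsWith(txt, "/gene=")) {
          cur$gene <- gsub("\"", "", sub("^/gene=", "", txt))
        } else if (startsWith(txt, "/locus_tag=")) {
          cur$locus_tag <- gsub("\"", "", sub("^/locus_tag=", "", txt))
        } else if (!startsWith(txt, "/")) {     # continued location
          cur$location <- paste0(cur$location, txt)
        }
      }
    }
  }
  out[[length(out) + 1L]] <- flush_feature(cur)
  ft <- do.call(rbind, out)
  if (is.null(ft)) {
    ft <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0), strand = character(0),
                     type = character(0), gene_id = character(0))
    return(ft)
  }
  ## mRNA features only carry gene ids for their exons in richer files;
  ## the minimal reader keeps gene/exon/CDS rows.
  ft <- ft[ft$type %in% c("gene", "exon", "CDS"), , drop = FALSE]
  ft
}

## "join(12..78,134..202)", "complement(4..60)", "90" -> 0-based half-open
## span(s). Multi-segment joins are expanded to one row per segment by the
## caller via parse_genbank_location_segments; the enclosing span is used
## for single features.
parse_genbank_location <- function(loc) {
  complement <- grepl("complement\\(", loc)
  loc <- gsub("complement\\(|join\\(|order\\(|\\)", "", loc)
  segs <- strsplit(loc, ",")[[1]]
  rng <- t(vapply(segs, function(s) {
    s <- gsub("[<>]", "", s)
    ab <- as.integer(strsplit(s, "\\.\\.")[[1]])
    if (length(ab) == 1L) ab <- c(ab, ab)
    ab
  }, integer(2)))
  list(start = min(rng[, 1]) - 1L, end = max(rng[, 2]),
       complement = complement)
}

region_set <- function(class, intervals) {
  intervals <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(class = class, intervals = intervals), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set '%s': %d interval(s), %s bp\n", x$class,
              nrow(x$intervals),
              format(sum(x$intervals$end - x$intervals$start),
                     big.mark = ",")))
  invisible(x)
}

## data.frame(chrom,start,end[,strand]) -> GRanges (1-based internally);
## a shared Seqinfo keeps multi-chromosome set operations warning-free
df_to_granges <- function(df, strand = NULL, seqinfo = NULL) {
  if (nrow(df) == 0L)
    return(GenomicRanges::GRanges(seqinfo = seqinfo))
  GenomicRanges::GRanges(
    seqnames = factor(df$chrom,
                      levels = if (is.null(seqinfo)) unique(df$chrom)
                               else GenomeInfoDb::seqnames(seqinfo)),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand %||% (if ("strand" %in% names(df)) df$strand else "*"),
    seqinfo = seqinfo)
}

granges_to_df <- function(gr) {
  if (length(gr) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)))
}

#' Derive the five region classes from a genome annotation
#'
#' Computes maximal-interval sets for the five region classes: `genic`
#' (union of gene spans), `exonic` (union of exons, merged per strand),
#' `CDS` (union of CDS intervals, merged per strand), `intronic` (per gene:
#' gene span minus that gene's exons, then minus all exons genome-wide, so
#' no base is both exonic and intronic even for overlapping genes) and
#' `intergenic` (chromosome complement of the gene-span union). Empty
#' classes are allowed.
#'
#' @param x a `genome` (from [load_genome()] or [generate_genome()]) or
#'   `genome_annotation`.
#' @return named list of five `region_set` objects.
#' @export
derive_regions <- function(x) {
  ann <- if (inherits(x, "genome")) x$annotation else x
  stopifnot(inherits(ann, "genome_annotation"))
  validate_annotation(ann)
  ft <- ann$features
  chr <- ann$chromosomes
  si <- GenomeInfoDb::Seqinfo(seqnames = chr$id, seqlengths = chr$length)
  genome_gr <- GenomicRanges::GRanges(
    seqnames = chr$id, ranges = IRanges::IRanges(start = 1, end = chr$length),
    seqinfo = si)
  genes <- ft[ft$type == "gene", , drop = FALSE]
  exons <- ft[ft$type == "exon", , drop = FALSE]
  cds <- ft[ft$type == "CDS", , drop = FALSE]
  gene_gr <- df_to_granges(genes, strand = "*", seqinfo = si)
  exon_gr_stranded <- df_to_granges(exons, seqinfo = si)
  cds_gr_stranded <- df_to_granges(cds, seqinfo = si)
  exon_union <- GenomicRanges::reduce(df_to_granges(exons, strand = "*",
                                                    seqinfo = si))
  genic <- GenomicRanges::reduce(gene_gr)
  intergenic <- GenomicRanges::setdiff(genome_gr, genic)
  intronic <- GenomicRanges::GRanges(seqinfo = si)
  if (nrow(genes) > 0L) {
    per_gene <- lapply(seq_len(nrow(genes)), function(i) {
      g <- df_to_granges(genes[i, , drop = FALSE], strand = "*", seqinfo = si)
      ex <- exons[exons$gene_id == genes$gene_id[i], , drop = FALSE]
      GenomicRanges::setdiff(g, GenomicRanges::reduce(
        df_to_granges(ex, strand = "*", seqinfo = si)))
    })
    intronic <- GenomicRanges::reduce(do.call(c, per_gene))
    intronic <- GenomicRanges::setdiff(intronic, exon_union)
  }
  list(
    genic = region_set("genic", granges_to_df(genic)),
    exonic = region_set("exonic",
                        granges_to_df(GenomicRanges::reduce(exon_gr_stranded))),
    CDS = region_set("CDS",
                     granges_to_df(GenomicRanges::reduce(cds_gr_stranded))),
    intronic = region_set("intronic", granges_to_df(intronic)),
    intergenic = region_set("intergenic", granges_to_df(intergenic))
  )
}

#' Region composition as percentages of genome length
#'
#' @param regions list of `region_set` objects (from [derive_regions()]).
#' @param genome_length total genome length in bp (sum over chromosomes).
#' @return data.frame with `region`, `bp`, `percent`; per-base unions are
#'   used so that genic + intergenic = 100 within rounding.
#' @export
region_composition <- function(regions, genome_length) {
  if (genome_length <= 0) stop("genome length must be positive")
  bp <- vapply(regions, function(rs) {
    gr <- GenomicRanges::reduce(df_to_granges(rs$intervals, strand = "*"))
    sum(GenomicRanges::width(gr))
  }, numeric(1))
  data.frame(region = names(regions), bp = unname(bp),
             percent = unname(100 * bp / genome_length), row.names = NULL)
}

#' Extract the sequences of a region set
#'
#' Default orientation policy: intronic and intergenic sequences are taken
#' from the forward assembly strand; exonic and CDS intervals annotated on
#' the minus strand are reverse-complemented (gene orientation), so that
#' codon-frame structure is preserved. `orientation = "forward"` keeps
#' everything on the assembly strand.
#'
#' @param regions a `region_set`.
#' @param sequences named `DNAStringSet` (or `genome` object).
#' @param orientation `"default"` or `"forward"`.
#' @return `DNAStringSet`, one sequence per maximal interval.
#' @export
extract_sequences <- function(regions, sequences, orientation = "default") {
  stopifnot(inherits(regions, "region_set"))
  if (inherits(sequences, "genome")) sequences <- sequences$sequences
  orientation <- match.arg(orientation, c("default", "forward"))
  iv <- regions$intervals
  if (nrow(iv) == 0L) return(Biostrings::DNAStringSet())
  out <- Biostrings::DNAStringSet(vapply(seq_len(nrow(iv)), function(i)
    as.character(Biostrings::subseq(sequences[[iv$chrom[i]]],
                                    start = iv$start[i] + 1L,
                                    end = iv$end[i])), character(1)))
  if (orientation == "default" && regions$class %in% c("exonic", "CDS")) {
    minus <- which(iv$strand == "-")
    if (length(minus))
      out[minus] <- Biostrings::reverseComplement(out[minus])
  }
  names(out) <- sprintf("%s_%s_%d_%d", regions$class, iv$chrom, iv$start,
                        iv$end)
  out
}

#' Export a region set as BED (0-based half-open)
#'
#' @param regions a `region_set`.
#' @param path output path.
#' @export
regions_to_bed <- function(regions, path) {
  iv <- regions$intervals
  strand <- if ("strand" %in% names(iv)) iv$strand else rep(".", nrow(iv))
  strand[!strand %in% c("+", "-")] <- "."
  df <- data.frame(iv$chrom, iv$start, iv$end,
                   sprintf("%s_%d", regions$class, seq_len(nrow(iv))),
                   0L, strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a genome annotation as GFF3
#'
#' Gene/exon/CDS features are emitted with `ID`/`Parent` attributes so that
#' re-loading with [load_genome()] reproduces the feature table.
#'
#' @param annotation a `genome_annotation` (or `genome`).
#' @param path output path.
#' @export
annotation_to_gff3 <- function(annotation, path) {
  if (inherits(annotation, "genome")) annotation <- annotation$annotation
  ft <- annotation$features
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", annotation$chromosomes$id,
                     annotation$chromosomes$length))
  if (nrow(ft) > 0L) {
    attr_col <- ifelse(ft$type == "gene",
                       sprintf("ID=%s", ft$gene_id),
                       sprintf("ID=%s.%s%d;Parent=%s", ft$gene_id,
                               tolower(ft$type), seq_len(nrow(ft)),
                               ft$gene_id))
    lines <- c(lines, sprintf("%s\tstrdecomp\t%s\t%d\t%d\t.\t%s\t.\t%s",
                              ft$chrom, ft$type, ft$start + 1L, ft$end,
                              ft$strand, attr_col))
  }
  writeLines(lines, path)
  invisible(path)
}
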