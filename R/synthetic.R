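#' Configuration for a synthetic annotated genome
#'
#' The generator emulates the genome structure the region/spectrum analysis
#' assumes: multi-chromosome assemblies, first-order Markov background at a
#' target G+C, non-overlapping genes with exon/intron structure, codon-like
#' period-3 bias inside CDS, and planted tandem-repeat tracts with
#' controlled single-base mismatch preferences.
#'
#' @param chromosomes named integer vector of chromosome lengths in bp.
#' @param gc target background G+C fraction.
#' @param lambda like-class persistence of the background Markov model
#'   (see [markov_model()]).
#' @param gene_density genes per Mbp.
#' @param exons_per_gene mean exon count per gene (>= 1).
#' @param mean_exon_length,mean_intron_length mean lengths in bp
#'   (geometric-tailed).
#' @param codon_bias strength in \[0, 1\] of the period-3 positional base
#'   bias used for CDS letters (0 = uniform codons).
#' @param str_planting list of planting specs; each a list with fields
#'   `region` (one of `intronic`, `intergenic`, `exonic`, `CDS`), `unit`
#'   (repeat unit, e.g. `"A"`, `"AT"`, `"GT"`), `rate_per_mbp` (tracts per
#'   Mbp of that region class), `min_len` (minimum tract length in bp,
#'   default 12), `mean_extension` (mean geometric extra length, default 3),
#'   `strand_mode` (`"symmetric"`: fixed unit phase, each tract
#'   reverse-complemented with probability 1/2; `"forward"`: forward strand
#'   only, random unit rotation per tract), `mismatch_rate` (per-base
#'   substitution probability inside the tract, default 0) and `pi` (named
#'   substitution preference over A/C/G/T, renormalized over bases
#'   different from the original at each position).
#' @param seed master seed; all randomness derives from it.
#' @return a `synthetic_genome_config` list.
#' @export
synthetic_genome_config <- function(chromosomes = c(chr1 = 500000L),
                                    gc = 0.40, lambda = 1.2,
                                    gene_density = 200,
                                    exons_per_gene = 4,
                                    mean_exon_length = 200,
                                    mean_intron_length = 400,
                                    codon_bias = 0.5,
                                    str_planting = list(),
                                    seed = 1) {
  if (is.null(names(chromosomes)))
    names(chromosomes) <- sprintf("chr%d", seq_along(chromosomes))
  str_planting <- lapply(str_planting, function(sp) {
    sp$min_len <- sp$min_len %||% 12L
    sp$mean_extension <- sp$mean_extension %||% 3
    sp$strand_mode <- match.arg(sp$strand_mode %||% "symmetric",
                                c("symmetric", "forward"))
    sp$mismatch_rate <- sp$mismatch_rate %||% 0
    if (sp$mismatch_rate < 0 || sp$rate_per_mbp < 0)
      stop("rates must be nonnegative")
    if (!is.null(sp$pi)) {
      if (abs(sum(sp$pi) - 1) > 1e-9) stop("pi must sum to 1")
      if (any(sp$pi < 0)) stop("pi must be nonnegative")
    }
    sp
  })
  structure(list(chromosomes = chromosomes, gc = gc, lambda = lambda,
                 gene_density = gene_density, exons_per_gene = exons_per_gene,
                 mean_exon_length = mean_exon_length,
                 mean_intron_length = mean_intron_length,
                 codon_bias = codon_bias, str_planting = str_planting,
                 seed = seed),
            class = "synthetic_genome_config")
}

## Period-3 positional base profile blended with uniform by `bias`.
codon_position_profile <- function(bias) {
  prof <- rbind(c(0.30, 0.20, 0.30, 0.20),   # codon position 1 (A,C,G,T)
                c(0.35, 0.20, 0.15, 0.30),   # position 2
                c(0.15, 0.30, 0.35, 0.20))   # position 3
  (1 - bias) * matrix(0.25, 3, 4) + bias * prof
}

sample_coding_sequence <- function(n, bias) {
  prof <- codon_position_profile(bias)
  pos <- (seq_len(n) - 1L) %% 3L + 1L
  out <- character(n)
  for (p in 1:3) {
    sel <- pos == p
    out[sel] <- sample(DNA_BASES, sum(sel), replace = TRUE, prob = prof[p, ])
  }
  paste0(out, collapse = "")
}

## lengths with geometric right tail: min + rgeom(mean tail)
rlen <- function(n, mean_len, min_len = 1) {
  tail_mean <- max(mean_len - min_len, 1)
  min_len + stats::rgeom(n, prob = 1 / (tail_mean + 1))
}

#' Generate a synthetic annotated genome
#'
#' Background is drawn from a first-order Markov model at the configured
#' G+C; genes are placed without overlap with exon/intron structure; exon
#' (CDS) letters are drawn from the period-3 codon profile in gene
#' orientation; tandem-repeat tracts are overwritten at sampled loci in the
#' requested region classes, with independent per-base substitution using
#' the preference vector `pi`. Ground truth lists every planted tract.
#' Identical seeds give identical output.
#'
#' @param config a `synthetic_genome_config`.
#' @param dir optional output directory; if given, writes `genome.fasta`,
#'   `genome.gff3`, `tracts.bed` and `truth.json`.
#' @return object of classes `synthetic_genome`/`genome`: list with
#'   `sequences`, `annotation`, `truth` (data.frame of planted tracts) and
#'   `config`.
#' @export
generate_genome <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_genome_config"))
  set.seed(config$seed)
  model <- markov_model(order = 1, gc = config$gc, lambda = config$lambda)
  chrs <- config$chromosomes
  chr_seeds <- sample.int(.Machine$integer.max - 1L, length(chrs))

  seqs <- list()
  features <- list()
  for (ci in seq_along(chrs)) {
    len <- as.integer(chrs[ci])
    id <- names(chrs)[ci]
    base <- strsplit(simulate_markov_sequence(model, len,
                                              seed = chr_seeds[ci]), "")[[1]]
    n_genes <- round(config$gene_density * len / 1e6)
    if (n_genes > 0) {
      structs <- lapply(seq_len(n_genes), function(g) {
        ne <- max(1L, stats::rpois(1, config$exons_per_gene - 1) + 1L)
        ex <- rlen(ne, config$mean_exon_length, min_len = 30)
        intr <- if (ne > 1) rlen(ne - 1L, config$mean_intron_length,
                                 min_len = 40) else integer(0)
        list(ex = ex, intr = intr, len = sum(ex) + sum(intr))
      })
      gene_bp <- sum(vapply(structs, function(s) s$len, numeric(1)))
      spare <- len - gene_bp
      if (spare < n_genes + 1)
        stop("infeasible config: genes exceed chromosome capacity")
      cuts <- sort(sample.int(spare - 1L, n_genes))
      gaps <- diff(c(0L, cuts, spare))
      pos <- 0L
      for (g in seq_len(n_genes)) {
        pos <- pos + gaps[g]
        s <- structs[[g]]
        gid <- sprintf("%s.g%04d", id, g)
        strand <- sample(c("+", "-"), 1)
        gstart <- pos
        ## exon/intron layout within the gene
        estart <- gstart
        exon_rows <- list()
        for (e in seq_along(s$ex)) {
          exon_rows[[e]] <- c(estart, estart + s$ex[e])
          estart <- estart + s$ex[e] +
            (if (e <= length(s$intr)) s$intr[e] else 0L)
        }
        gend <- gstart + s$len
        ## coding letters across exons, period-3 in gene orientation
        total_ex <- sum(s$ex)
        cds_seq <- sample_coding_sequence(total_ex, config$codon_bias)
        if (strand == "-")
          cds_seq <- reverse_complement(cds_seq)
        ## on the forward assembly strand, fill exons in genomic order
        cds_ch <- strsplit(cds_seq, "")[[1]]
        off <- 0L
        for (e in seq_along(exon_rows)) {
          w <- exon_rows[[e]][2] - exon_rows[[e]][1]
          base[(exon_rows[[e]][1] + 1):(exon_rows[[e]][2])] <-
            cds_ch[(off + 1):(off + w)]
          off <- off + w
        }
        features[[length(features) + 1L]] <- data.frame(
          chrom = id,
          start = c(gstart, vapply(exon_rows, `[`, numeric(1), 1),
                    vapply(exon_rows, `[`, numeric(1), 1)),
          end = c(gend, vapply(exon_rows, `[`, numeric(1), 2),
                  vapply(exon_rows, `[`, numeric(1), 2)),
          strand = strand,
          type = c("gene", rep("exon", length(exon_rows)),
                   rep("CDS", length(exon_rows))),
          gene_id = gid)
        pos <- gend
      }
    }
    seqs[[id]] <- base
  }
  chromosomes <- data.frame(id = names(chrs), length = as.integer(chrs))
  features <- if (length(features)) do.call(rbind, features) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), type = character(0),
               gene_id = character(0))
  ann <- genome_annotation(chromosomes, features)

  ## plant STR tracts
  truth <- list()
  if (length(config$str_planting) > 0) {
    regions <- derive_regions(ann)
    occupied <- list()  # per chrom: matrix of placed tract intervals
    for (si in seq_along(config$str_planting)) {
      sp <- config$str_planting[[si]]
      iv <- regions[[sp$region]]$intervals
      widths <- iv$end - iv$start
      class_bp <- sum(widths)
      n_tracts <- stats::rpois(1, sp$rate_per_mbp * class_bp / 1e6)
      if (n_tracts == 0) next
      mean_tract <- sp$min_len + sp$mean_extension
      if (n_tracts * mean_tract > 0.5 * class_bp)
        stop(sprintf(
          "infeasible config: planted %s tracts exceed %s region capacity",
          sp$unit, sp$region))
      b <- nchar(sp$unit)
      placed <- 0L
      tries <- 0L
      while (placed < n_tracts && tries < 50L * n_tracts) {
        tries <- tries + 1L
        tlen <- sp$min_len + stats::rgeom(1, 1 / (sp$mean_extension + 1))
        i <- sample.int(nrow(iv), 1, prob = widths)
        if (widths[i] < tlen) next
        start <- iv$start[i] + sample.int(widths[i] - tlen + 1L, 1) - 1L
        chrom <- iv$chrom[i]
        prev <- occupied[[chrom]]
        if (!is.null(prev) &&
            any(start < prev[, 2] & start + tlen > prev[, 1])) next
        occupied[[chrom]] <- rbind(prev, c(start, start + tlen))
        ## build tract letters
        if (sp$strand_mode == "forward") {
          rot <- sample.int(b, 1) - 1L
          tract <- substr(strrep(sp$unit, ceiling((tlen + rot) / b) + 1L),
                          rot + 1L, rot + tlen)
          tract_strand <- "+"
        } else {
          tract <- substr(strrep(sp$unit, ceiling(tlen / b)), 1L, tlen)
          if (stats::runif(1) < 0.5) {
            tract <- reverse_complement(tract)
            tract_strand <- "-"
          } else tract_strand <- "+"
        }
        tr_ch <- strsplit(tract, "")[[1]]
        ## planted tracts are maximal repeats: a flanking background base
        ## that would extend the repeat pattern is replaced, so tract
        ## boundaries are sharp (as for a maximal repeat locus)
        stat_p <- model$p
        if (start >= 1L) {
          left_ext <- tr_ch[b]
          if (seqs[[chrom]][start] == left_ext) {
            alt <- setdiff(DNA_BASES, left_ext)
            seqs[[chrom]][start] <- sample(alt, 1,
                                           prob = stat_p[match(alt, DNA_BASES)])
          }
        }
        if (start + tlen + 1L <= length(seqs[[chrom]])) {
          right_ext <- tr_ch[tlen - b + 1L]
          if (seqs[[chrom]][start + tlen + 1L] == right_ext) {
            alt <- setdiff(DNA_BASES, right_ext)
            seqs[[chrom]][start + tlen + 1L] <-
              sample(alt, 1, prob = stat_p[match(alt, DNA_BASES)])
          }
        }
        n_mm <- 0L
        mm_bases <- character(0)
        if (sp$mismatch_rate > 0 && !is.null(sp$pi)) {
          hit <- which(stats::runif(tlen) < sp$mismatch_rate)
          for (h in hit) {
            p <- sp$pi[setdiff(DNA_BASES, tr_ch[h])]
            if (sum(p) <= 0) next
            tr_ch[h] <- sample(names(p), 1, prob = p / sum(p))
            n_mm <- n_mm + 1L
            mm_bases <- c(mm_bases, tr_ch[h])
          }
        }
        seqs[[chrom]][(start + 1):(start + tlen)] <- tr_ch
        truth[[length(truth) + 1L]] <- data.frame(
          chrom = chrom, start = start, end = start + tlen,
          unit = sp$unit, region = sp$region, strand = tract_strand,
          n_mismatches = n_mm,
          mismatch_bases = paste(mm_bases, collapse = ""))
        placed <- placed + 1L
      }
      if (placed < n_tracts)
        stop(sprintf(
          "infeasible config: could not place %d %s tracts in %s regions",
          n_tracts, sp$unit, sp$region))
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               unit = character(0), region = character(0),
               strand = character(0), n_mismatches = integer(0),
               mismatch_bases = character(0))

  sequences <- Biostrings::DNAStringSet(
    vapply(seqs, paste0, character(1), collapse = ""))
  genome <- structure(list(sequences = sequences, annotation = ann,
                           truth = truth, config = config),
                      class = c("synthetic_genome", "genome"))
  if (!is.null(dir)) write_synthetic_genome(genome, dir)
  genome
}

#' Write a synthetic genome to disk (FASTA + GFF3 + ground truth)
#'
#' @param genome a `synthetic_genome`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_synthetic_genome <- function(genome, dir) {
  stopifnot(inherits(genome, "synthetic_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(genome$sequences, file.path(dir, "genome.fasta"))
  annotation_to_gff3(genome$annotation, file.path(dir, "genome.gff3"))
  tr <- genome$truth
  bed <- data.frame(tr$chrom, tr$start, tr$end,
                    sprintf("%s_%s", tr$unit, tr$region),
                    rep(0L, nrow(tr)), ifelse(tr$strand == "-", "-", "+"))
  utils::write.table(bed, file.path(dir, "tracts.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(tr, file.path(dir, "truth.json"), dataframe = "rows")
  invisible(dir)
}

#' Verify that a synthetic genome realizes its configuration
#'
#' Checks realized G+C, region composition, the k-mer excess of each
#' planted family word over the Markov background expectation in its target
#' region class, and the realized mismatch base frequencies against the
#' configured preference vector `pi`.
#'
#' @param genome a `synthetic_genome`.
#' @param k word length for the planted-word excess check (default 7).
#' @return list with `gc` (target, realized), `composition`,
#'   `planting` (per spec: word, observed and expected counts, excess
#'   ratio), `mismatches` (per spec: observed base fractions and `pi`).
#' @export
emulation_report <- function(genome, k = 7) {
  stopifnot(inherits(genome, "synthetic_genome"))
  config <- genome$config
  regions <- derive_regions(genome$annotation)
  comp <- region_composition(regions, sum(config$chromosomes))
  model <- markov_model(order = 1, gc = config$gc, lambda = config$lambda)
  planting <- lapply(config$str_planting, function(sp) {
    seqs <- extract_sequences(regions[[sp$region]], genome$sequences,
                              orientation = "forward")
    spx <- compute_spectrum(seqs, k)
    word <- substr(strrep(sp$unit, k), 1L, k)
    obs <- unname(spectrum_counts(spx, word))
    expd <- expected_markov_spectrum(model, k, spx$total_windows + k - 1)
    expc <- unname(spectrum_counts(expd, word))
    data.frame(region = sp$region, unit = sp$unit, word = word,
               observed = obs, expected = expc,
               excess = if (expc > 0) obs / expc else NA_real_)
  })
  mism <- lapply(config$str_planting, function(sp) {
    tr <- genome$truth[genome$truth$unit == sp$unit &
                         genome$truth$region == sp$region, ]
    bases <- unlist(strsplit(paste0(tr$mismatch_bases, collapse = ""), ""))
    if (length(bases) == 0 || is.null(sp$pi)) return(NULL)
    obs <- table(factor(bases, levels = DNA_BASES)) / length(bases)
    data.frame(region = sp$region, unit = sp$unit, base = DNA_BASES,
               observed = as.numeric(obs),
               pi = as.numeric(sp$pi[DNA_BASES]))
  })
  list(gc = c(target = config$gc,
              realized = gc_fraction(genome$sequences)),
       composition = comp,
       planting = if (length(planting)) do.call(rbind, planting) else NULL,
       mismatches = mism[!vapply(mism, is.null, logical(1))])
}
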