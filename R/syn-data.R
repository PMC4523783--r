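#' Specification of a synthetic small-RNA study
#'
#' Describes a toy genome with planted miRNA hairpins and ncRNA contaminant
#' loci, emulating the structure of a two-library (NCT = control at 25 degrees C,
#' CT = cold-treated at 4 degrees C) grapevine small-RNA experiment: a reference
#' genome, a known-miRNA reference with mature and precursor sequences, novel
#' hairpin loci that satisfy the ten-rule precursor criteria by construction,
#' and rRNA/tRNA/snRNA/snoRNA/repeat loci that source contaminant reads.
#'
#' @param genome_length total genome length in bases (split over chromosomes).
#' @param n_chromosomes number of chromosomes.
#' @param n_known_loci,n_novel_loci,n_ncrna_loci planted locus counts.
#' @param gc_fraction genome GC content.
#' @param seed integer seed; the same spec yields byte-identical output.
#' @param abundance_range expected read-count range per miRNA locus
#'   (log-uniform draw).
#' @param dem_fraction fraction of miRNA loci planted as differentially
#'   expressed between the libraries.
#' @param dem_fold fold difference planted for DEM loci.
#' @param exclusive_fraction fraction of novel DEM loci made library-exclusive
#'   (count 0 in the low library), emulating reported CT-only/NCT-only novel
#'   miRNAs.
#' @return list of class `syn_genome_spec`.
#' @export
synthetic_genome_spec <- function(genome_length = 120000, n_chromosomes = 2,
                                  n_known_loci = 8, n_novel_loci = 6,
                                  n_ncrna_loci = 10, gc_fraction = 0.46,
                                  seed = 1, abundance_range = c(60, 3000),
                                  dem_fraction = 0.3, dem_fold = 4,
                                  exclusive_fraction = 0.2) {
  stopifnot(genome_length > 0, n_chromosomes >= 1, gc_fraction >= 0,
            gc_fraction <= 1, dem_fold >= 1)
  structure(list(
    genome_length = as.integer(genome_length),
    n_chromosomes = as.integer(n_chromosomes),
    n_known_loci = as.integer(n_known_loci),
    n_novel_loci = as.integer(n_novel_loci),
    n_ncrna_loci = as.integer(n_ncrna_loci),
    gc_fraction = gc_fraction, seed = as.integer(seed),
    abundance_range = abundance_range, dem_fraction = dem_fraction,
    dem_fold = dem_fold, exclusive_fraction = exclusive_fraction
  ), class = "syn_genome_spec")
}

# grapevine-style family names used for synthetic known miRNAs
KNOWN_FAMILY_POOL <- c("miR156", "miR159", "miR166", "miR169", "miR172",
                       "miR395", "miR396", "miR397", "miR398", "miR399",
                       "miR3623", "miR3624", "miR3633", "miR3634", "miR3636",
                       "miR3640")

# Build a hairpin around a mature sequence: star = reverse complement with
# 0-2 injected substitutions, loop of 8-15 nt, 20-nt flanks on both sides.
make_hairpin <- function(mature, gc = 0.46, flank = 20) {
  loop_len <- sample(8:15, 1)
  n_mm <- sample(0:2, 1)
  star <- mutate_seq(revcomp(mature), n_mm)
  arm <- sample(c("5p", "3p"), 1)
  loop <- random_seq(1, loop_len, gc)
  core <- if (arm == "5p") paste0(mature, loop, star) else paste0(star, loop, mature)
  f5 <- random_seq(1, flank, gc)
  f3 <- random_seq(1, flank, gc)
  mature_offset <- if (arm == "5p") flank + 1L else flank + nchar(star) + loop_len + 1L
  list(precursor = paste0(f5, core, f3), mature_offset = as.integer(mature_offset),
       star = star, arm = arm)
}

# genomic interval occupied by the mature, given the planted precursor
mature_genomic_coords <- function(pos, prec_len, offset, mat_len, strand) {
  if (strand == "+") {
    c(pos + offset - 1L, pos + offset + mat_len - 2L)
  } else {
    c(pos + prec_len - (offset + mat_len - 1L), pos + prec_len - offset)
  }
}

#' Build a synthetic genome with planted loci and ground truth
#'
#' Plants known-family hairpins, novel hairpins and ncRNA loci into a random
#' background genome. Each novel hairpin is verified in situ: the
#' discovery-shaped precursor window around the planted mature is excised,
#' folded with `backend` and required to pass all ten criteria of
#' [check_criteria()]; failing draws are redrawn (bounded retries), so planted
#' novel loci are positive controls by construction.
#'
#' @param spec a [synthetic_genome_spec()].
#' @param backend folding backend used for in-situ verification.
#' @param max_tries redraw budget per novel locus.
#' @return list with `genome` (named character vector), `truth` (data.frame of
#'   planted loci), `known_mature`, `known_precursor`, `ncrna` (named
#'   character vectors), `annotation` (data.frame of GFF-style features) and
#'   `spec`.
#' @export
build_genome <- function(spec, backend = fold_backend_default(), max_tries = 40) {
  stopifnot(inherits(spec, "syn_genome_spec"))
  set.seed(spec$seed)
  n_chrom <- spec$n_chromosomes
  chrom_len <- rep(spec$genome_length %/% n_chrom, n_chrom)
  chrom_names <- paste0("chr", seq_len(n_chrom))
  genome <- setNames(random_seq(n_chrom, chrom_len, spec$gc_fraction), chrom_names)

  # --- locus plan -----------------------------------------------------------
  n_mirna <- spec$n_known_loci + spec$n_novel_loci
  n_total <- n_mirna + spec$n_ncrna_loci
  ncrna_cats <- c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat")
  ncrna_lens <- c(rRNA = 160, tRNA = 80, snRNA = 130, snoRNA = 100, repeat_ = 220)
  plan <- data.frame(
    locus_id = paste0("locus_", seq_len(n_total)),
    category = c(rep("known_miRNA", spec$n_known_loci),
                 rep("novel_miRNA", spec$n_novel_loci),
                 if (spec$n_ncrna_loci)
                   ncrna_cats[1 + (seq_len(spec$n_ncrna_loci) - 1) %% length(ncrna_cats)]
                 else character(0)),
    stringsAsFactors = FALSE
  )
  plan$length <- ifelse(plan$category %in% c("known_miRNA", "novel_miRNA"),
                        120L,  # reserve; actual precursors are <= ~110 nt
                        as.integer(ncrna_lens[match(plan$category, names(ncrna_lens),
                                                    nomatch = 5)]))
  plan$chrom <- chrom_names[1 + (seq_len(n_total) - 1) %% n_chrom]

  # --- packing: place loci with >= 60 nt spacing ----------------------------
  margin <- 80L
  plan$pos <- NA_integer_
  for (ch in chrom_names) {
    rows <- which(plan$chrom == ch)
    if (!length(rows)) next
    need <- sum(plan$length[rows] + 60L) + 2L * margin
    if (need > chrom_len[match(ch, chrom_names)]) {
      stop("infeasible packing: planted loci exceed capacity of ", ch)
    }
    slack <- chrom_len[match(ch, chrom_names)] - need
    gaps <- as.vector(stats::rmultinom(1, slack, rep(1, length(rows) + 1)))
    pos <- margin + gaps[1] + 1L
    for (k in seq_along(rows)) {
      plan$pos[rows[k]] <- pos
      pos <- pos + plan$length[rows[k]] + 60L + gaps[k + 1]
    }
  }

  # --- known miRNA families -------------------------------------------------
  fams <- character(0)
  if (spec$n_known_loci > 0) {
    base <- sample(KNOWN_FAMILY_POOL, min(length(KNOWN_FAMILY_POOL),
                                          max(1, ceiling(spec$n_known_loci / 2))))
    fams <- sort(rep_len(base, spec$n_known_loci))
  }
  fam_letter <- unlist(lapply(unique(fams), function(f) letters[seq_len(sum(fams == f))]))
  known_names <- if (length(fams)) paste0("vvi-", fams, fam_letter) else character(0)

  truth <- vector("list", n_total)
  known_mature <- character(0)
  known_precursor <- character(0)
  ncrna <- character(0)
  thresholds <- novel_criteria_thresholds()

  splice <- function(chrom, pos, seq) {
    g <- genome[[chrom]]
    substr(g, pos, pos + nchar(seq) - 1L) <- seq
    genome[[chrom]] <<- g
  }

  mi <- 0L  # known-family counter
  fam_seq <- list() # family -> reference mature (members differ by 1-2 nt)
  for (i in seq_len(n_total)) {
    cat_i <- plan$category[i]
    strand <- sample(c("+", "-"), 1)
    if (cat_i %in% c("known_miRNA", "novel_miRNA")) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        if (cat_i == "known_miRNA") {
          fam <- fams[mi + 1L]
          if (is.null(fam_seq[[fam]])) {
            # 21-nt dominant mature class, as in leaf small-RNA libraries
            mature <- random_seq(1, sample(20:22, 1, prob = c(.15, .7, .15)), 0.5)
            fam_seq[[fam]] <- mature
          } else {
            mature <- mutate_seq(fam_seq[[fam]], sample(1:2, 1))
          }
        } else {
          mature <- random_seq(1, sample(20:23, 1, prob = c(.1, .6, .2, .1)), 0.5)
        }
        hp <- make_hairpin(mature, spec$gc_fraction, thresholds$flank)
        gseq <- if (strand == "+") hp$precursor else revcomp(hp$precursor)
        splice(plan$chrom[i], plan$pos[i], gseq)
        # in-situ verification in discovery geometry
        mc <- mature_genomic_coords(plan$pos[i], nchar(hp$precursor),
                                    hp$mature_offset, nchar(mature), strand)
        cl <- data.frame(chrom = plan$chrom[i], start = mc[1], end = mc[2],
                         strand = strand, tag = mature,
                         tag_start = mc[1], tag_end = mc[2],
                         stringsAsFactors = FALSE)
        wins <- excise_candidates(cl, genome, flank = thresholds$flank,
                                  max_space = thresholds$max_space)
        folded <- fold_rna(wins$precursor_seq, backend)
        pass_any <- FALSE
        for (w in seq_len(nrow(wins))) {
          dup <- find_duplex(folded$structure[w], wins$mature_offset[w], nchar(mature))
          if (!dup$ok) next
          cand <- list(mature_seq = mature, mfe = folded$mfe[w],
                       duplex_stats = dup$stats, n_genomic_copies = 1L,
                       flank = thresholds$flank)
          if (attr(check_criteria(cand, c(NCT = 100, CT = 100), thresholds),
                   "overall")) pass_any <- TRUE
        }
        # mature must be genome-unique (criterion 3 with copies = 1)
        n_cop <- sum(vapply(genome, function(g) {
          length(gregexpr(mature, g, fixed = TRUE)[[1]][
            gregexpr(mature, g, fixed = TRUE)[[1]] > 0]) +
          length(gregexpr(revcomp(mature), g, fixed = TRUE)[[1]][
            gregexpr(revcomp(mature), g, fixed = TRUE)[[1]] > 0])
        }, numeric(1)))
        if (pass_any && n_cop == 1L) { ok <- TRUE; break }
      }
      if (!ok) stop("could not plant a criteria-passing hairpin at locus ",
                    plan$locus_id[i], " after ", max_tries, " tries")
      if (cat_i == "known_miRNA") {
        mi <- mi + 1L
        nm <- known_names[mi]
        known_mature[nm] <- mature
        known_precursor[paste0(nm, "-precursor")] <- hp$precursor
      } else {
        nm <- paste0("novel_true_", i)
      }
      truth[[i]] <- data.frame(
        locus_id = plan$locus_id[i], name = nm, category = cat_i,
        chrom = plan$chrom[i], start = plan$pos[i],
        end = plan$pos[i] + nchar(hp$precursor) - 1L, strand = strand,
        mature_seq = mature, star_seq = hp$star,
        precursor_seq = hp$precursor, mature_offset = hp$mature_offset,
        stringsAsFactors = FALSE
      )
    } else {
      seq <- random_seq(1, plan$length[i], spec$gc_fraction)
      gseq <- if (strand == "+") seq else revcomp(seq)
      splice(plan$chrom[i], plan$pos[i], gseq)
      nm <- paste0(sub("_$", "", cat_i), "_", i)
      ncrna[paste0(cat_i, "|", nm)] <- seq
      truth[[i]] <- data.frame(
        locus_id = plan$locus_id[i], name = nm, category = cat_i,
        chrom = plan$chrom[i], start = plan$pos[i],
        end = plan$pos[i] + plan$length[i] - 1L, strand = strand,
        mature_seq = NA_character_, star_seq = NA_character_,
        precursor_seq = seq, mature_offset = NA_integer_,
        stringsAsFactors = FALSE
      )
    }
  }
  truth <- do.call(rbind, truth)

  # --- abundances -----------------------------------------------------------
  is_mirna <- truth$category %in% c("known_miRNA", "novel_miRNA")
  lam <- exp(runif(n_total, log(spec$abundance_range[1]), log(spec$abundance_range[2])))
  is_dem <- is_mirna & runif(n_total) < spec$dem_fraction
  up <- runif(n_total) < 0.5
  ab_nct <- ifelse(is_dem & up, lam, ifelse(is_dem, lam * spec$dem_fold, lam))
  ab_ct <- ifelse(is_dem & up, lam * spec$dem_fold, ifelse(is_dem, lam, lam))
  excl <- is_dem & truth$category == "novel_miRNA" &
    runif(n_total) < spec$exclusive_fraction
  ab_nct[excl & up] <- 0
  ab_ct[excl & !up] <- 0
  # ncRNA loci: abundance columns are relative contaminant weights
  w <- runif(n_total, 0.3, 1)
  ab_nct[!is_mirna] <- w[!is_mirna]
  ab_ct[!is_mirna] <- w[!is_mirna]
  truth$abundance_NCT <- round(ab_nct, 3)
  truth$abundance_CT <- round(ab_ct, 3)
  truth$is_dem <- is_dem

  # --- annotation features (ncRNA loci + two exon features on free ground) --
  ann <- truth[!is_mirna, c("chrom", "start", "end", "strand", "category", "name")]
  names(ann)[names(ann) == "category"] <- "type"
  ex <- data.frame(chrom = chrom_names[1],
                   start = c(11L, 41L), end = c(40L, 70L),
                   strand = "+", type = c("exon", "intron"),
                   name = c("gene1.exon1", "gene1.intron1"),
                   stringsAsFactors = FALSE)
  annotation <- rbind(ann, ex)
  rownames(annotation) <- NULL

  list(genome = genome, truth = truth, known_mature = known_mature,
       known_precursor = known_precursor, ncrna = ncrna,
       annotation = annotation, spec = spec)
}

#' Read-simulation parameters
#'
#' @param total_reads nominal library size; scales contaminant and background
#'   read counts (miRNA locus reads are absolute Poisson draws around the
#'   planted abundances).
#' @param adapter_3p 3' sequencing adapter appended to inserts shorter than
#'   the read length (default: the common small-RNA TruSeq adapter).
#' @param read_length sequencing cycle length (nt).
#' @param length_noise_prob per-end probability of an isomiR offset.
#' @param length_noise_geom geometric parameter of the offset magnitude.
#' @param error_rate per-base substitution probability.
#' @param contaminant_fraction fraction of `total_reads` drawn as ncRNA
#'   fragments (sized with a 24-nt mode, producing the 21/24-nt bimodal tag
#'   length profile typical of plant leaf libraries).
#' @param junk_fraction fraction of `total_reads` drawn as random genomic
#'   background fragments.
#' @param n_base_fraction,low_quality_fraction fractions of reads given an N
#'   call / a uniformly low quality string (exercising the cleaning filters).
#' @param qual_char constant Phred+33 quality character for normal reads.
#' @param seed integer seed.
#' @export
read_sim_params <- function(total_reads = 200000,
                            adapter_3p = "TGGAATTCTCGGGTGCCAAGG",
                            read_length = 50,
                            length_noise_prob = 0.1, length_noise_geom = 0.6,
                            error_rate = 0.001, contaminant_fraction = 0.3,
                            junk_fraction = 0.05, n_base_fraction = 0.002,
                            low_quality_fraction = 0.002, qual_char = "I",
                            seed = 1) {
  stopifnot(nchar(adapter_3p) >= 6, error_rate >= 0, error_rate <= 1,
            contaminant_fraction >= 0, contaminant_fraction <= 1)
  structure(list(total_reads = as.integer(total_reads), adapter_3p = adapter_3p,
                 read_length = as.integer(read_length),
                 length_noise_prob = length_noise_prob,
                 length_noise_geom = length_noise_geom,
                 error_rate = error_rate,
                 contaminant_fraction = contaminant_fraction,
                 junk_fraction = junk_fraction,
                 n_base_fraction = n_base_fraction,
                 low_quality_fraction = low_quality_fraction,
                 qual_char = qual_char, seed = as.integer(seed)),
            class = "read_sim_params")
}

# truncated-geometric isomiR end offsets, signed
draw_offsets <- function(n, prob, geom_p, max_off = 2L) {
  off <- integer(n)
  hit <- runif(n) < prob
  k <- sum(hit)
  if (k) {
    mag <- pmin(1L + stats::rgeom(k, geom_p), max_off)
    off[hit] <- mag * sample(c(-1L, 1L), k, replace = TRUE)
  }
  off
}

# 18-30 nt fragment lengths with a 24-nt mode (siRNA-like size class)
draw_frag_lengths <- function(n) {
  lens <- 18:30
  sample(lens, n, replace = TRUE, prob = stats::dnorm(lens, 24, 1.2))
}

#' Simulate one small-RNA library
#'
#' Draws Poisson read counts for each planted miRNA locus around its
#' abundance in the selected library, generates isomiR end variants from the
#' precursor context, adds ncRNA contaminant fragments and genomic background
#' reads, appends the 3' adapter, and injects sequencing errors, N calls and
#' low-quality reads.
#'
#' @param syn output of [build_genome()].
#' @param params a [read_sim_params()].
#' @param library_name "NCT" or "CT" (selects the abundance column).
#' @return object of class `srna_library`: list with `library`, `seq`,
#'   `qual`, `origin` (locus name, "contaminant" or "background"),
#'   `insert_len`, `params`.
#' @export
simulate_library <- function(syn, params, library_name = c("NCT", "CT")) {
  library_name <- match.arg(library_name)
  truth <- syn$truth
  col <- paste0("abundance_", library_name)
  if (!col %in% names(truth)) stop("abundance column missing: ", col)
  set.seed(params$seed + 7919L * match(library_name, c("NCT", "CT")))

  is_mirna <- truth$category %in% c("known_miRNA", "novel_miRNA")
  mir <- truth[is_mirna, , drop = FALSE]
  counts <- rpois(nrow(mir), mir[[col]])

  inserts <- character(0); origin <- character(0)
  for (i in seq_len(nrow(mir))) {
    n_i <- counts[i]
    if (n_i == 0) next
    o <- mir$mature_offset[i]; L <- nchar(mir$mature_seq[i])
    P <- nchar(mir$precursor_seq[i])
    d5 <- draw_offsets(n_i, params$length_noise_prob, params$length_noise_geom)
    d3 <- draw_offsets(n_i, params$length_noise_prob, params$length_noise_geom)
    s <- pmax(1L, o + d5); e <- pmin(P, o + L - 1L + d3)
    inserts <- c(inserts, substring(mir$precursor_seq[i], s, e))
    origin <- c(origin, rep(mir$name[i], n_i))
  }

  nc <- truth[!is_mirna, , drop = FALSE]
  n_cont <- round(params$contaminant_fraction * params$total_reads)
  if (n_cont > 0 && nrow(nc) > 0) {
    pick <- sample(nrow(nc), n_cont, replace = TRUE, prob = nc[[col]])
    fl <- draw_frag_lengths(n_cont)
    fl <- pmin(fl, nchar(nc$precursor_seq[pick]))
    st <- 1L + floor(runif(n_cont) * (nchar(nc$precursor_seq[pick]) - fl + 1L))
    inserts <- c(inserts, substring(nc$precursor_seq[pick], st, st + fl - 1L))
    origin <- c(origin, rep("contaminant", n_cont))
  }

  n_junk <- round(params$junk_fraction * params$total_reads)
  if (n_junk > 0) {
    chrom <- sample(names(syn$genome), n_junk, replace = TRUE,
                    prob = nchar(syn$genome))
    fl <- draw_frag_lengths(n_junk)
    st <- 1L + floor(runif(n_junk) * (nchar(syn$genome)[match(chrom, names(syn$genome))] - fl))
    frag <- substring(syn$genome[chrom], st, st + fl - 1L)
    flip <- runif(n_junk) < 0.5
    frag[flip] <- revcomp(frag[flip])
    inserts <- c(inserts, frag)
    origin <- c(origin, rep("background", n_junk))
  }

  insert_len <- nchar(inserts)
  reads <- substr(paste0(inserts, params$adapter_3p), 1L, params$read_length)

  # sequencing errors (vectorised for the dominant single-error case)
  if (params$error_rate > 0) {
    k <- rbinom(length(reads), nchar(reads), params$error_rate)
    one <- which(k == 1L)
    if (length(one)) {
      pos <- 1L + floor(runif(length(one)) * nchar(reads[one]))
      old <- substr(reads[one], pos, pos)
      sub <- DNA_BASES[1L + (match(old, DNA_BASES, nomatch = 1L) +
                             floor(runif(length(one)) * 3)) %% 4L]
      substr(reads[one], pos, pos) <- sub
    }
    for (j in which(k > 1L)) reads[j] <- mutate_seq(reads[j], k[j])
  }
  # N calls
  nn <- round(params$n_base_fraction * length(reads))
  if (nn > 0) {
    j <- sample(length(reads), nn)
    pos <- 1L + floor(runif(nn) * nchar(reads[j]))
    substr(reads[j], pos, pos) <- "N"
    reads[j] <- reads[j]
  }
  qual <- strrep(params$qual_char, nchar(reads))
  nl <- round(params$low_quality_fraction * length(reads))
  if (nl > 0) {
    j <- sample(length(reads), nl)
    qual[j] <- strrep("#", nchar(reads[j]))
  }
  perm <- sample(length(reads))
  structure(list(library = library_name, seq = reads[perm], qual = qual[perm],
                 origin = origin[perm], insert_len = insert_len[perm],
                 params = params),
            class = "srna_library")
}

#' Write a simulated library as FASTQ (Phred+33, gzip by extension)
#'
#' @param lib an `srna_library`.
#' @param path output path; gzip-compressed if it ends in `.gz`.
#' @export
write_fastq <- function(lib, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  ids <- paste0("@", lib$library, "_r", seq_along(lib$seq))
  writeLines(paste(ids, lib$seq, "+", lib$qual, sep = "\n"), con)
  invisible(path)
}

#' Write the synthetic data bundle to a directory
#'
#' Emits the genome FASTA, the ground-truth TSV, the known-miRNA reference
#' FASTA (`>name` for matures, `>name-precursor` for hairpins), the ncRNA
#' category FASTA and the annotation GFF3.
#'
#' @param syn output of [build_genome()].
#' @param dir output directory (created if missing).
#' @export
write_synthetic_data <- function(syn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(syn$genome, file.path(dir, "genome.fa"))
  tr <- syn$truth
  tr$location <- format_locus(tr$chrom, tr$start, tr$end, tr$strand)
  tr$mature_seq <- to_rna(tr$mature_seq)
  tr$star_seq <- to_rna(tr$star_seq)
  write.table(tr[, c("locus_id", "name", "category", "location", "mature_seq",
                     "star_seq", "abundance_NCT", "abundance_CT")],
              file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_fasta(c(syn$known_mature, syn$known_precursor),
              file.path(dir, "known_mirna.fa"))
  if (length(syn$ncrna)) write_fasta(syn$ncrna, file.path(dir, "ncrna.fa"))
  ann <- syn$annotation
  gr <- GenomicRanges::GRanges(ann$chrom, IRanges::IRanges(ann$start, ann$end),
                               strand = ann$strand, type = ann$type, ID = ann$name)
  rtracklayer::export(gr, file.path(dir, "annotation.gff3"), format = "gff3")
  invisible(dir)
}
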