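# Synthetic tripartite genome + ChIP library generator with planted truth.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: three circular replicons of very different sizes (1/10 the real
# scale), genes on both strands, GC-skew sign switching at ori/ter, 13
# insertion-sequence copies carrying the exact 25-nt insertion-site query
# with its flanking 25-mers, uniform input libraries, IP libraries
# with enrichment peaks whose positions decay exponentially with circular
# distance to ori and whose host-gene strands are biased toward the
# lagging-strand template, and optional read depletion at the insertion
# site in the active-RNP constructs.

#' Default synthetic study configuration
#'
#' Defaults describe a 1/10-scale tripartite rhizobial genome (chromosome
#' 365 kb, two megaplasmid-like replicons of 147 kb and 161 kb), 13 planted
#' IS copies, 100 planted binding-site peaks at 8-fold enrichment whose
#' positions decay exponentially from ori (scale 20 kb) with a 0.70
#' lagging-template host-strand probability, 20x mean fragment coverage per
#' library, 75-bp reads from 300-bp fragments, and 50% insertion-site read
#' depletion in the IP fractions of the active-RNP constructs.
#'
#' @param replicons data.frame with columns `name, length, ori, ter`.
#' @param gc genome GC fraction.
#' @param skew GC-skew amplitude `s`: G/C base probabilities are
#'   `gc/2 * (1 +/- s)` with sign `+s` on the ori->ter coordinate-increasing
#'   arm and `-s` on the other arm.
#' @param gene_density target coding fraction of each replicon.
#' @param mean_gene_len mean gene length in bp.
#' @param n_is_copies number of planted IS cassettes genome-wide.
#' @param n_true_peaks number of planted binding-site peaks genome-wide.
#' @param n_decoy_peaks decoy peaks per control construct (placed disjoint
#'   from the true peaks and from each other, so the expected unique-peak
#'   set equals the planted set exactly); `NULL` means `n_true_peaks`,
#'   which balances total library sizes across constructs.
#' @param peak_enrichment fold enrichment of IP coverage at planted peaks.
#' @param peak_len_range planted peak length range in bp.
#' @param ori_decay_scale exponential scale (bp) of the circular distance
#'   from ori at which peaks are planted; `Inf` places peaks uniformly.
#' @param p_lag probability that a planted peak's host gene lies on the
#'   lagging-strand template.
#' @param depth_input,depth_ip mean extended-fragment coverage of input and
#'   IP libraries.
#' @param read_length,fragment_length read and sonication-fragment lengths
#'   in bp.
#' @param deplete_insertion_site fraction of reads spanning the intact
#'   insertion-site 25-mer removed from the IP libraries of the
#'   active-RNP constructs, emulating site interruption by intron
#'   insertion during retrohoming (`0` disables depletion). Reads over
#'   the flanking 25-mers are untouched, which is what makes the flanks
#'   usable as scan controls.
#' @param placement_margin guard distance in bp kept between planted true
#'   peaks and the decoy peaks / IS cassettes. Called peak boundaries
#'   bleed up to about a fragment length beyond the planted interval, so
#'   without this margin a control-construct call can brush a true peak
#'   and the subtraction filter would remove it; the margin keeps the
#'   expected unique-peak set equal to the planted set.
#' @param seed integer RNG seed threaded through all generators.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    replicons = data.frame(
      name = c("chromosome", "pSymA", "pSymB"),
      length = c(365000, 147000, 161000),
      ori = c(91000, 37000, 40000),
      ter = c(273500, 110500, 120500),
      stringsAsFactors = FALSE),
    gc = 0.62,
    skew = 0.05,
    gene_density = 0.85,
    mean_gene_len = 900,
    n_is_copies = 13,
    n_true_peaks = 100,
    n_decoy_peaks = NULL,
    peak_enrichment = 8,
    peak_len_range = c(200, 600),
    ori_decay_scale = 20000,
    p_lag = 0.70,
    depth_input = 20,
    depth_ip = 20,
    read_length = 75,
    fragment_length = 300,
    deplete_insertion_site = 0.5,
    placement_margin = 600,
    seed = 1L) {
  if (is.null(n_decoy_peaks)) n_decoy_peaks <- n_true_peaks
  stopifnot(p_lag >= 0, p_lag <= 1, gc > 0, gc < 1, skew >= 0, skew < 1,
            all(replicons$length > 0), all(replicons$ori != replicons$ter),
            peak_enrichment >= 1, depth_input > 0, depth_ip > 0,
            read_length > 0, fragment_length >= read_length,
            deplete_insertion_site >= 0, deplete_insertion_site <= 1,
            ori_decay_scale > 0)
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  cfg
}

# The three canonical 25-nt queries at the natural homing locus: the intron
# insertion site and sequences 50 nt upstream/downstream of it.
#' Insertion-site and flanking 25-nt site queries
#'
#' @return data.frame with columns `name, sequence` (three 25-mers).
#' @export
site_queries <- function() {
  data.frame(
    name = c("insertion_site", "upstream_50", "downstream_50"),
    sequence = c("CCTCGTTTTCATCGATGAGACCTGG",
                 "CGAACGGGAGCGGCCCGACGTCGCC",
                 "ACTGGTGGGCTACGCCCCCTTCGGC"),
    stringsAsFactors = FALSE)
}

# Sample planted peak center positions: circular distance to ori drawn
# Exponential(scale) truncated at L/2, arm chosen by fair coin;
# scale = Inf gives the uniform law.
#' @keywords internal
sample_ori_biased_positions <- function(n, L, ori, scale) {
  if (n == 0) return(numeric(0))
  if (!is.finite(scale)) {
    return(sample.int(L, n, replace = TRUE) - 1)
  }
  d <- stats::rexp(n, rate = 1 / scale)
  while (any(bad <- d > L / 2)) {
    d[bad] <- stats::rexp(sum(bad), rate = 1 / scale)
  }
  arm <- sample(c(1, -1), n, replace = TRUE)
  (ori + arm * floor(d)) %% L
}

# Per-base GC-skew sign along a replicon: +1 on the ori->ter
# coordinate-increasing arm, -1 on the other arm.
skew_sign <- function(L, ori, ter) {
  pos <- seq_len(L) - 1
  a <- (pos - ori) %% L
  b <- (ter - ori) %% L
  ifelse(a > 0 & a < b, 1, -1)
}

generate_sequence <- function(L, ori, ter, gc, skew) {
  sgn <- skew_sign(L, ori, ter) * skew
  pA <- (1 - gc) / 2
  pG <- gc / 2 * (1 + sgn)
  u <- stats::runif(L)
  base <- ifelse(u < pA, "A",
          ifelse(u < 2 * pA, "T",
          ifelse(u < 2 * pA + pG, "G", "C")))
  paste(base, collapse = "")
}

generate_genes <- function(rep_name, L, gene_density, mean_gene_len) {
  mean_gap <- max(20, mean_gene_len * (1 - gene_density) / gene_density)
  cursor <- floor(stats::runif(1, 0, mean_gap * 2))
  starts <- ends <- numeric(0)
  repeat {
    glen <- round(stats::rgamma(1, shape = 3, scale = mean_gene_len / 3))
    glen <- max(150, min(glen, 4000))
    if (cursor + glen > L - 10) break
    starts <- c(starts, cursor)
    ends <- c(ends, cursor + glen)
    gap <- 20 + round(stats::rexp(1, rate = 1 / mean_gap))
    cursor <- cursor + glen + gap
  }
  n <- length(starts)
  if (n == 0) stop_format("replicon %s too short for any gene", rep_name)
  data.frame(
    replicon = rep_name,
    start = starts, end = ends,
    strand = sample(c("+", "-"), n, replace = TRUE),
    gene_id = sprintf("%s_g%04d", rep_name, seq_len(n)),
    stringsAsFactors = FALSE)
}

# Occupancy-based rejection placement of an interval of length `len` on a
# circle of length L. Returns the unwrapped start, or NA after max tries.
place_disjoint <- function(occ, center, len, L) {
  s <- (center - len %/% 2) %% L
  idx <- ((s + seq_len(len) - 1) %% L) + 1
  if (any(occ[idx])) return(NULL)
  list(start = s, idx = idx)
}

#' Generate a synthetic multi-replicon genome with planted truth
#'
#' Produces replicon sequences with the configured GC-skew geometry,
#' non-overlapping genes on both strands, planted binding-site peaks
#' (hosted in genes whose strand realizes the configured lagging-template
#' probability), two disjoint decoy peak sets for the control constructs,
#' and IS cassettes each carrying the exact insertion-site 25-mer flanked
#' by the upstream/downstream flanking 25-mers 50 nt away.
#'
#' @param cfg a [synthetic_config()].
#' @param make_sequence generate actual DNA sequences (set `FALSE` to skip
#'   sequence synthesis when only placements are needed).
#' @return list with elements `replicons` (a [replicon_set()] with
#'   sequences), `genes`, and `truth` (list of data.frames `peaks`,
#'   `decoys_iep`, `decoys_untagged`, `is_copies`).
#' @export
generate_genome <- function(cfg, make_sequence = TRUE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed, generate_genome_impl(cfg, make_sequence))
}

generate_genome_impl <- function(cfg, make_sequence) {
  reps <- cfg$replicons
  nrep <- nrow(reps)

  seqs <- rep(NA_character_, nrep)
  if (make_sequence) {
    for (i in seq_len(nrep)) {
      seqs[i] <- generate_sequence(reps$length[i], reps$ori[i], reps$ter[i],
                                   cfg$gc, cfg$skew)
    }
  }

  genes <- do.call(rbind, lapply(seq_len(nrep), function(i) {
    generate_genes(reps$name[i], reps$length[i],
                   cfg$gene_density, cfg$mean_gene_len)
  }))

  # occupancy trackers: `occ` marks exactly placed intervals (everything
  # planted stays mutually disjoint); `guard` marks peak intervals dilated
  # by placement_margin, which decoys and IS cassettes must also avoid
  occ <- lapply(reps$length, function(L) rep(FALSE, L))
  names(occ) <- reps$name
  guard <- lapply(reps$length, function(L) rep(FALSE, L))
  names(guard) <- reps$name
  guard_idx <- function(s, len, L) {
    m <- cfg$placement_margin
    ((s - m + seq_len(len + 2 * m) - 1) %% L) + 1
  }

  # allocate peak counts across replicons proportional to length
  alloc <- function(n) {
    if (n == 0) return(rep(0, nrep))
    as.vector(stats::rmultinom(1, n, prob = reps$length))
  }

  strand_locked <- setNames(rep(FALSE, nrow(genes)), genes$gene_id)

  plant_peaks <- function(n_on, rep_i, genic, p_lag) {
    L <- reps$length[rep_i]; ori <- reps$ori[rep_i]; ter <- reps$ter[rep_i]
    rn <- reps$name[rep_i]
    g <- genes[genes$replicon == rn, , drop = FALSE]
    out <- vector("list", n_on)
    placed <- 0
    tries <- 0
    while (placed < n_on) {
      tries <- tries + 1
      if (tries > 200 * n_on + 1000) {
        stop_format("cannot place %d disjoint peaks on replicon %s", n_on, rn)
      }
      # exponential ori-proximity law; fall back to uniform when the
      # ori-proximal arm is saturated
      scale <- if (tries <= 50 * n_on) cfg$ori_decay_scale else Inf
      center <- sample_ori_biased_positions(1, L, ori, scale)
      plen <- round(stats::runif(1, cfg$peak_len_range[1], cfg$peak_len_range[2]))
      host <- NA_character_; host_strand <- NA_character_
      if (genic) {
        # host the peak in a gene: use the gene containing the center, else
        # snap the center to the nearest gene interior
        inside <- which(g$start <= center & center < g$end)
        gi <- if (length(inside)) inside[1] else {
          mids <- (g$start + g$end) / 2
          which.min(circular_distance(pmin(pmax(center, 0), L - 1), mids %% L, L))
        }
        center <- round((g$start[gi] + g$end[gi]) / 2 +
                          stats::runif(1, -0.3, 0.3) * (g$end[gi] - g$start[gi]))
        host <- g$gene_id[gi]
      }
      pl <- place_disjoint(occ[[rep_i]], center, plen, L)
      if (is.null(pl)) next
      occ[[rep_i]][pl$idx] <<- TRUE
      guard[[rep_i]][guard_idx(pl$start, plen, L)] <<- TRUE
      if (genic) {
        # realize the lagging-template bias through the host gene strand
        mid <- circ_midpoint(pl$start, pl$start + plen, L)
        d <- fork_direction(mid, L = L, ori = ori, ter = ter)
        lag_strand <- if (d == "CW") "+" else if (d == "CCW") "-" else NA
        if (!strand_locked[[host]] && !is.na(lag_strand)) {
          want_lag <- stats::runif(1) < p_lag
          genes$strand[genes$gene_id == host] <<-
            if (want_lag) lag_strand else setdiff(c("+", "-"), lag_strand)
          strand_locked[[host]] <<- TRUE
        }
        host_strand <- genes$strand[genes$gene_id == host]
        label <- if (is.na(lag_strand)) "ND"
                 else if (host_strand == lag_strand) "LAG" else "LEAD"
      } else {
        label <- NA_character_
      }
      placed <- placed + 1
      out[[placed]] <- data.frame(
        replicon = rn, start = pl$start, end = pl$start + plen,
        host_gene = host, host_strand = host_strand, fork_label = label,
        enrichment = cfg$peak_enrichment, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }

  n_true_by_rep <- alloc(cfg$n_true_peaks)
  peaks <- do.call(rbind, lapply(seq_len(nrep), function(i) {
    plant_peaks(n_true_by_rep[i], i, genic = TRUE, p_lag = cfg$p_lag)
  }))

  plant_decoys <- function() {
    n_by_rep <- alloc(cfg$n_decoy_peaks)
    do.call(rbind, lapply(seq_len(nrep), function(i) {
      if (n_by_rep[i] == 0) return(NULL)
      L <- reps$length[i]
      out <- vector("list", n_by_rep[i]); placed <- 0; tries <- 0
      while (placed < n_by_rep[i]) {
        tries <- tries + 1
        if (tries > 200 * n_by_rep[i] + 1000) {
          stop_format("cannot place decoy peaks on replicon %s", reps$name[i])
        }
        center <- sample.int(L, 1) - 1
        plen <- round(stats::runif(1, cfg$peak_len_range[1],
                                   cfg$peak_len_range[2]))
        pl <- place_disjoint(guard[[i]], center, plen, L)
        if (is.null(pl) || any(occ[[i]][pl$idx])) next
        occ[[i]][pl$idx] <<- TRUE
        guard[[i]][guard_idx(pl$start, plen, L)] <<- TRUE
        placed <- placed + 1
        out[[placed]] <- data.frame(
          replicon = reps$name[i], start = pl$start, end = pl$start + plen,
          enrichment = cfg$peak_enrichment, stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    }))
  }
  decoys_iep <- plant_decoys()
  decoys_untagged <- plant_decoys()

  # IS cassettes: upstream 25-mer at -50, insertion-site 25-mer, downstream
  # 25-mer starting +50 from the site start (125-bp cassette)
  q <- site_queries()
  qseq <- setNames(q$sequence, q$name)
  cassette_len <- 125
  is_by_rep <- alloc(cfg$n_is_copies)
  is_rows <- list()
  for (i in seq_len(nrep)) {
    L <- reps$length[i]
    placed <- 0; tries <- 0
    while (placed < is_by_rep[i]) {
      tries <- tries + 1
      if (tries > 5000) stop_format("cannot place IS cassettes on %s", reps$name[i])
      s <- sample.int(L - cassette_len, 1) - 1  # no seam wrap for cassettes
      idx <- (s + 1):(s + cassette_len)
      if (any(occ[[i]][idx]) || any(guard[[i]][idx])) next
      occ[[i]][idx] <- TRUE
      filler1 <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
                       collapse = "")
      filler2 <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
                       collapse = "")
      cassette <- paste0(qseq[["upstream_50"]], filler1,
                         qseq[["insertion_site"]], filler2,
                         qseq[["downstream_50"]])
      if (make_sequence) {
        substr(seqs[i], s + 1, s + cassette_len) <- cassette
      }
      placed <- placed + 1
      is_rows[[length(is_rows) + 1]] <- data.frame(
        replicon = reps$name[i],
        cassette_start = s, cassette_end = s + cassette_len,
        site_start = s + 50, site_end = s + 75,
        stringsAsFactors = FALSE)
    }
  }
  is_copies <- do.call(rbind, is_rows)

  replicons <- replicon_set(reps$name, reps$length, reps$ori, reps$ter,
                            sequence = seqs)
  list(replicons = replicons,
       genes = genes,
       truth = list(peaks = peaks,
                    decoys_iep = decoys_iep,
                    decoys_untagged = decoys_untagged,
                    is_copies = is_copies))
}

# split an unwrapped interval vector into placement rows with shared ids
make_placements <- function(rep_name, a, len, strand, L, id0 = 0L) {
  a <- a %% L
  b <- a + len
  wrap <- b > L
  id <- id0 + seq_along(a)
  o <- order(c(id, id[wrap]))
  df <- data.frame(
    replicon = rep_name,
    start = c(a, rep(0, sum(wrap)))[o],
    end = c(pmin(b, L), b[wrap] - L)[o],
    strand = c(strand, strand[wrap])[o],
    id = c(id, id[wrap])[o],
    stringsAsFactors = FALSE)
  df
}

#' Generate the 18 synthetic read-placement libraries
#'
#' Input libraries are uniform over each replicon at `depth_input`. The IP
#' library of the tagged-RNP construct receives extra fragments at the
#' planted true peaks at fold `peak_enrichment`; the IP libraries of the
#' two control constructs receive extra fragments only at their own
#' disjoint decoy peak sets, which is what the construct-subtraction
#' filter is designed to remove. When `deplete_insertion_site > 0`, that
#' fraction of fragments overlapping the insertion-site 25-mer is removed
#' from the IP libraries of the two active-RNP constructs.
#'
#' @param genome result of [generate_genome()].
#' @param cfg the [synthetic_config()] used to generate `genome`.
#' @param keys optional subset of `library_keys()$key` to generate
#'   (default: all 18).
#' @return named list of placement data.frames (columns
#'   `replicon, start, end, strand, id`), names as in
#'   `library_keys()$key`.
#' @export
generate_reads <- function(genome, cfg, keys = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  seed2 <- (cfg$seed %% 2000000000) + 1000001
  withr::with_seed(seed2, generate_reads_impl(genome, cfg, keys))
}

generate_reads_impl <- function(genome, cfg, subset_keys = NULL) {
  reps <- genome$replicons
  truth <- genome$truth
  keys <- library_keys()
  if (!is.null(subset_keys)) {
    stopifnot(all(subset_keys %in% keys$key))
    keys <- keys[keys$key %in% subset_keys, , drop = FALSE]
  }
  frag <- cfg$fragment_length
  rl <- cfg$read_length
  enr_sets <- list(pKG4_FlagIEP = truth$peaks,
                   pKG_FlagIEP = truth$decoys_iep,
                   pKGEMA4 = truth$decoys_untagged)
  active <- c("pKG4_FlagIEP", "pKGEMA4")

  libs <- vector("list", nrow(keys))
  names(libs) <- keys$key
  for (k in seq_len(nrow(keys))) {
    construct <- keys$construct[k]
    fraction <- keys$fraction[k]
    depth <- if (fraction == "input") cfg$depth_input else cfg$depth_ip
    parts <- list()
    for (i in seq_len(nrow(reps))) {
      L <- reps$length[i]
      rn <- reps$name[i]
      n_bg <- stats::rpois(1, depth * L / frag)
      fs <- sample.int(L, n_bg, replace = TRUE) - 1
      strand <- sample(c("+", "-"), n_bg, replace = TRUE)
      if (fraction == "IP" && cfg$peak_enrichment > 1) {
        pk <- enr_sets[[construct]]
        pk <- pk[pk$replicon == rn, , drop = FALSE]
        if (nrow(pk) > 0) {
          plen <- pk$end - pk$start
          lam <- (pk$enrichment - 1) * depth * (plen + frag) / frag
          n_extra <- stats::rpois(nrow(pk), lam)
          if (sum(n_extra) > 0) {
            # fragment must overlap the peak: start in (pstart-frag, pend)
            lo <- rep(pk$start - frag + 1, n_extra)
            span <- rep(plen + frag - 1, n_extra)
            fs_x <- (lo + floor(stats::runif(sum(n_extra)) * span)) %% L
            fs <- c(fs, fs_x)
            strand <- c(strand, sample(c("+", "-"), sum(n_extra),
                                       replace = TRUE))
          }
        }
      }
      # read occupies the 5'-most read_length bp of the fragment in read
      # orientation: [fs, fs+rl) on +, [fs+frag-rl, fs+frag) on -
      a <- ifelse(strand == "+", fs, fs + frag - rl)
      # insertion-site depletion in active-RNP IP libraries: intron
      # insertion interrupts the site, so reads spanning the intact
      # 25-mer junction disappear; reads over the flanks survive
      if (fraction == "IP" && cfg$deplete_insertion_site > 0 &&
          construct %in% active && !is.null(truth$is_copies)) {
        sites <- truth$is_copies[truth$is_copies$replicon == rn, , drop = FALSE]
        if (nrow(sites) > 0 && length(a) > 0) {
          hit <- rep(FALSE, length(a))
          for (s in seq_len(nrow(sites))) {
            # read [a, a+rl) fully covers site [ss, se) circularly
            ss <- sites$site_start[s]; se <- sites$site_end[s]
            hit <- hit | (((ss - a) %% L) <= (rl - (se - ss)))
          }
          drop <- hit & (stats::runif(length(a)) < cfg$deplete_insertion_site)
          a <- a[!drop]; strand <- strand[!drop]
        }
      }
      parts[[rn]] <- make_placements(rn, a, rl, strand, L,
                                     id0 = sum(vapply(parts, function(p)
                                       length(unique(p$id)), integer(1))))
    }
    libs[[keys$key[k]]] <- do.call(rbind, parts)
    rownames(libs[[keys$key[k]]]) <- NULL
  }
  libs
}

#' Extract read sequences for a placement library
#'
#' Reads on the minus strand are reverse-complemented; seam-wrapped reads
#' (two placement rows sharing an id) are re-joined before extraction.
#'
#' @param placements placement data.frame from [generate_reads()].
#' @param replicons a [replicon_set()] carrying sequences.
#' @return character vector of read sequences, one per read id.
#' @export
read_sequences <- function(placements, replicons) {
  rns <- unique(placements$replicon)
  parts <- vector("list", length(rns))
  for (j in seq_along(rns)) {
    rn <- rns[j]
    rr <- replicon_row(replicons, rn)
    if (is.na(rr$sequence)) stop_format("replicon %s has no sequence", rn)
    L <- rr$length
    sel <- placements$replicon == rn
    uw <- unwrap_vectors(placements$start[sel], placements$end[sel],
                         placements$strand[sel], placements$id[sel], L)
    s1 <- pmin(uw$end, L)
    seqs <- substring(rr$sequence, uw$start + 1, s1)
    wrapped <- uw$end > L
    if (any(wrapped)) {
      seqs[wrapped] <- paste0(seqs[wrapped],
                              substring(rr$sequence, 1, uw$end[wrapped] - L))
    }
    minus <- uw$strand == "-"
    if (any(minus)) seqs[minus] <- revcomp_many(seqs[minus])
    parts[[j]] <- seqs
  }
  unlist(parts, use.names = FALSE)
}

#' Write a synthetic bundle to disk
#'
#' Emits the genome FASTA, gene GFF3, replicon config, one BED6 per
#' library, and the truth tables as TSV.
#'
#' @param genome result of [generate_genome()].
#' @param libs result of [generate_reads()].
#' @param dir output directory (created if needed).
#' @param fastq also emit per-library FASTQ files of read sequences.
#' @return `dir`, invisibly.
#' @export
write_synthetic_bundle <- function(genome, libs, dir, fastq = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- setNames(genome$replicons$sequence, genome$replicons$name)
  if (!anyNA(seqs)) write_fasta(seqs, file.path(dir, "genome.fasta"))
  write_gff3(genome$genes, file.path(dir, "genes.gff3"))
  write_replicon_config(genome$replicons, file.path(dir, "replicons.tsv"))
  for (key in names(libs)) {
    df <- libs[[key]]
    df$name <- paste0("read_", df$id)
    df$score <- 0
    write_bed(df[, c("replicon", "start", "end", "name", "score", "strand")],
              file.path(dir, paste0(key, ".bed")))
    if (fastq && !anyNA(seqs)) {
      rs <- read_sequences(df, genome$replicons)
      con <- file(file.path(dir, paste0(key, ".fastq")), "w")
      writeLines(paste0("@", key, "_read_", seq_along(rs), "\n", rs, "\n+\n",
                        strrep("I", nchar(rs))), con)
      close(con)
    }
  }
  for (tab in names(genome$truth)) {
    if (!is.null(genome$truth[[tab]])) {
      utils::write.table(genome$truth[[tab]],
                         file.path(dir, paste0("truth_", tab, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}
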