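#' Simulation configuration
#'
#' Defaults emulate the study conditions of the guided-assembly experiments
#' at desk scale: XhoI restriction sites planted at a mean spacing of 10 kb
#' (so a typical read spans about one fragment and a typical contig spans
#' many, as in the genome-scale setting), 40x read coverage, log-normal read
#' lengths with mean 8.2 kb (the simulated PacBio regime), a 0.5 % total
#' error rate standing in for error-corrected long reads, and noise-free
#' genome-wide optical maps.
#'
#' @param seed Integer seed; every simulator operation is a pure function of
#'   its inputs and this seed.
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Chromosome length in bp.
#' @param site_density Planted restriction sites per bp (exponential
#'   spacing with mean `1/site_density`).
#' @param coverage Target read coverage (reads are drawn until the summed
#'   length reaches `coverage * genome length`).
#' @param read_length_mean,read_length_sd Mean and standard deviation of the
#'   log-normal read-length distribution, in bp.
#' @param error_mismatch,error_insertion,error_deletion Per-base error
#'   fractions, each in `[0, 1)`.
#' @param map_sizing_sd Optical-map sizing standard deviation per kb
#'   (fragment lengths scaled by `Normal(1, sd)`).
#' @param map_missing_cut_prob Probability that a cut is missed (adjacent
#'   fragments merged).
#' @param map_false_cut_per_kb Poisson rate of spurious extra cuts per kb.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 2L,
                              chromosome_length = 150000L,
                              site_density = 1 / 10000,
                              coverage = 40,
                              read_length_mean = 8200,
                              read_length_sd = 3000,
                              error_mismatch = 0.003,
                              error_insertion = 0.001,
                              error_deletion = 0.001,
                              map_sizing_sd = 0,
                              map_missing_cut_prob = 0,
                              map_false_cut_per_kb = 0) {
  rates <- c(error_mismatch, error_insertion, error_deletion,
             map_missing_cut_prob)
  stopifnot(all(rates >= 0), all(rates < 1), coverage > 0,
            chromosome_length > 0, read_length_mean > 0, n_chromosomes >= 1)
  structure(
    list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
         chromosome_length = as.integer(chromosome_length),
         site_density = site_density, coverage = coverage,
         read_length_mean = read_length_mean,
         read_length_sd = read_length_sd,
         error_mismatch = error_mismatch,
         error_insertion = error_insertion,
         error_deletion = error_deletion,
         map_sizing_sd = map_sizing_sd,
         map_missing_cut_prob = map_missing_cut_prob,
         map_false_cut_per_kb = map_false_cut_per_kb),
    class = "simulation_config"
  )
}

with_sim_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a genome with planted restriction sites
#'
#' Uniform random DNA per chromosome with the enzyme motif planted at
#' exponential spacings of mean `1/site_density` (default one site per 10 kb). Spontaneous motif
#' occurrences arising in the random background are disrupted by a
#' single-base change, so the realized restriction-site density — and hence
#' the optical map's fragment-length distribution — follows the configured
#' spacing exactly (in a real genome this quantity is fixed by the
#' sequence; the simulator has to control it).
#'
#' @param cfg A [simulation_config()].
#' @param enzyme A [restriction_enzyme()] whose motif is planted.
#' @return A named `DNAStringSet` (chromosomes `chr0`, `chr1`, ...).
#' @export
simulate_genome <- function(cfg, enzyme = xhoi()) {
  motif <- enzyme$motif
  mlen <- nchar(motif)
  if (1 / cfg$site_density < 2 * mlen) {
    abort("site density too high: motifs cannot fit at that spacing")
  }
  mchars <- strsplit(motif, "")[[1L]]
  with_sim_seed(cfg$seed, {
    seqs <- vapply(seq_len(cfg$n_chromosomes), function(k) {
      L <- cfg$chromosome_length
      gaps <- rexp(ceiling(L * cfg$site_density * 3) + 10L,
                   rate = cfg$site_density)
      starts <- round(cumsum(gaps + mlen)) - mlen
      starts <- unique(starts[starts + mlen <= L - 1 & starts >= 1])
      chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      for (s0 in starts) {
        chars[(s0 + 1):(s0 + mlen)] <- mchars
      }
      in_planted <- logical(L)
      for (s0 in starts) in_planted[(s0 + 1):(s0 + mlen)] <- TRUE
      # disrupt spontaneous occurrences without touching planted sites
      for (pass in 1:10) {
        seq <- paste(chars, collapse = "")
        occ <- motif_starts(seq, motif)
        extra <- setdiff(occ, starts)
        if (length(extra) == 0L) break
        for (s0 in extra) {
          cand <- (s0 + 1):(s0 + mlen)
          cand <- cand[!in_planted[cand]]
          if (length(cand) == 0L) next  # overlaps a planted site; leave it
          p <- cand[ceiling(length(cand) / 2)]
          chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
        }
      }
      paste(chars, collapse = "")
    }, character(1L))
    Biostrings::DNAStringSet(
      setNames(seqs, paste0("chr", seq_len(cfg$n_chromosomes) - 1L))
    )
  })
}

#' Simulate long reads with ground truth
#'
#' Reads are drawn until the summed read length reaches
#' `coverage * genome length`: a chromosome is chosen proportionally to its
#' length, a log-normal read length is drawn (resampled if longer than the
#' chromosome), the start is uniform, the strand fair, and per-base errors
#' are applied (substitutions first, then insertions and deletions at
#' uniform positions). Truth records store the exact sampled interval
#' (0-based half-open) and strand.
#'
#' @param genome A `DNAStringSet` (or FASTA path).
#' @param cfg A [simulation_config()].
#' @return List with `reads` (named `DNAStringSet`) and `truth` (tibble
#'   `read_id`, `chromosome`, `start`, `end`, `strand`).
#' @export
simulate_reads <- function(genome, cfg) {
  genome <- as_dna(genome)
  if (length(genome) == 0L) abort("genome is empty")
  lens <- Biostrings::width(genome)
  target <- cfg$coverage * sum(lens)
  meanlog <- log(cfg$read_length_mean) -
    0.5 * log(1 + (cfg$read_length_sd / cfg$read_length_mean)^2)
  sdlog <- sqrt(log(1 + (cfg$read_length_sd / cfg$read_length_mean)^2))
  with_sim_seed(cfg$seed + 1L, {
    reads <- character(0)
    truth <- list()
    total <- 0
    i <- 0L
    while (total < target) {
      i <- i + 1L
      repeat {
        rl <- max(200L, round(rlnorm(1L, meanlog, sdlog)))
        chrom <- sample.int(length(genome), 1L, prob = lens)
        if (rl <= lens[chrom]) break
      }
      start <- sample.int(lens[chrom] - rl + 1L, 1L) - 1L
      strand <- sample(c("+", "-"), 1L)
      s <- as.character(Biostrings::subseq(genome[[chrom]], start + 1L,
                                           start + rl))
      if (strand == "-") s <- revcomp(s)
      s <- apply_read_errors(s, cfg)
      id <- sprintf("read%05d", i)
      reads[id] <- s
      truth[[i]] <- tibble(read_id = id,
                           chromosome = names(genome)[chrom],
                           start = as.integer(start),
                           end = as.integer(start + rl), strand = strand)
      total <- total + rl
    }
    list(reads = Biostrings::DNAStringSet(reads), truth = bind_rows(truth))
  })
}

# substitutions, then insertions, then deletions, at uniform positions
apply_read_errors <- function(s, cfg) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(s, "")[[1L]]
  n <- length(chars)
  nsub <- stats::rbinom(1L, n, cfg$error_mismatch)
  if (nsub > 0L) {
    pos <- sample.int(n, nsub)
    chars[pos] <- vapply(chars[pos], function(b) {
      sample(setdiff(bases, b), 1L)
    }, character(1L))
  }
  nins <- stats::rbinom(1L, n, cfg$error_insertion)
  if (nins > 0L) {
    pos <- sort(sample.int(n + 1L, nins, replace = TRUE))
    ins <- sample(bases, nins, replace = TRUE)
    out <- character(n + nins)
    src <- 1L
    dst <- 1L
    insk <- 1L
    for (p in seq_len(n + 1L)) {
      while (insk <= nins && pos[insk] == p) {
        out[dst] <- ins[insk]
        dst <- dst + 1L
        insk <- insk + 1L
      }
      if (p <= n) {
        out[dst] <- chars[p]
        dst <- dst + 1L
      }
    }
    chars <- out
    n <- length(chars)
  }
  ndel <- stats::rbinom(1L, n, cfg$error_deletion)
  if (ndel > 0L && ndel < n) {
    chars <- chars[-sample.int(n, ndel)]
  }
  paste(chars, collapse = "")
}

#' Plant a shared repeat across two chromosomes
#'
#' Copies a segment of one chromosome over a segment of another (lengths
#' preserved), creating an exact interspersed repeat. Reads sampled across
#' the two copies then produce spurious cross-chromosome overlaps — the
#' failure mode that color guidance is designed to remove.
#'
#' @param genome A named `DNAStringSet`.
#' @param from_chrom,from_start Source chromosome name and 0-based start.
#' @param to_chrom,to_start Destination chromosome name and 0-based start.
#' @param repeat_length Length of the copied segment in bp.
#' @return The modified `DNAStringSet`.
#' @export
plant_repeat <- function(genome, from_chrom, from_start, to_chrom, to_start,
                         repeat_length) {
  seqs <- as.character(genome)
  seg <- substr(seqs[[from_chrom]], from_start + 1L,
                from_start + repeat_length)
  if (nchar(seg) < repeat_length) abort("source segment out of range")
  dst <- seqs[[to_chrom]]
  if (to_start + repeat_length > nchar(dst)) {
    abort("destination segment out of range")
  }
  seqs[[to_chrom]] <- paste0(
    substr(dst, 1L, to_start),
    seg,
    substr(dst, to_start + repeat_length + 1L, nchar(dst))
  )
  Biostrings::DNAStringSet(seqs)
}

#' Perturb an optical map with measurement noise
#'
#' Fragment lengths are scaled by `Normal(1, map_sizing_sd)` (truncated to
#' stay positive), adjacent fragments are merged with probability
#' `map_missing_cut_prob` per internal cut, and spurious cuts are inserted
#' as a Poisson process per kb, splitting fragments uniformly. With all
#' noise terms zero the map is returned unchanged; merges and splits alone
#' conserve total length exactly.
#'
#' @param map A single-map tibble.
#' @param cfg A [simulation_config()] carrying the `map_*` noise terms.
#' @param seed Integer seed.
#' @return A perturbed map tibble.
#' @export
perturb_map <- function(map, cfg, seed = cfg$seed) {
  lens <- map_lengths(map)
  with_sim_seed(seed + 2L, {
    if (cfg$map_missing_cut_prob > 0 && length(lens) > 1L) {
      miss <- runif(length(lens) - 1L) < cfg$map_missing_cut_prob
      grp <- cumsum(c(1L, !miss))
      lens <- as.numeric(tapply(lens, grp, sum))
    }
    if (cfg$map_false_cut_per_kb > 0) {
      out <- list()
      for (l in lens) {
        ncut <- rpois(1L, cfg$map_false_cut_per_kb * l / 1000)
        if (ncut > 0L) {
          cuts <- sort(runif(ncut, 0, l))
          out[[length(out) + 1L]] <- diff(c(0, cuts, l))
        } else {
          out[[length(out) + 1L]] <- l
        }
      }
      lens <- unlist(out)
    }
    if (cfg$map_sizing_sd > 0) {
      scale <- rnorm(length(lens), 1, cfg$map_sizing_sd)
      scale <- pmax(scale, 0.05)
      lens <- lens * scale
    }
    optical_map(map$map_id[1L], map$enzyme[1L], lens)
  })
}
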