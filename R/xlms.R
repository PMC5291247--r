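#' Monoisotopic masses
#'
#' Residue masses (Da) for the 20 canonical amino acids, plus the constants
#' used throughout the cross-link search.
#' @export
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

#' @rdname AA_MONO
#' @export
MASS_WATER <- 18.0105646863

#' @rdname AA_MONO
#' @export
MASS_PROTON <- 1.00727646677

MASS_H1 <- 1.00782503207
MASS_H2 <- 2.01410177785

#' Isotope-coded amine-reactive cross-linker description
#'
#' BS2G (bis(sulfosuccinimidyl) glutarate) bridges primary amines (lysine
#' side chains and protein N-termini) with a 7.7 A spacer. Reaction of both
#' NHS esters leaves a glutaryl bridge, composition C5H4O2
#' (96.02113 Da monoisotopic); the d4 form carries four deuteriums, shifting
#' the bridge by `4 * (2H - 1H) = 4.02511 Da`.
#'
#' @param name linker name.
#' @param bridge_mass_light monoisotopic bridge mass, Da.
#' @param n_heavy_isotopes number of H -> 2H substitutions in the heavy form.
#' @param spacer_length Angstrom.
#' @return object of class `xl_linker`.
#' @export
linker_bs2g <- function(name = "BS2G-d0/d4",
                        bridge_mass_light = 5 * 12 + 4 * MASS_H1 +
                          2 * 15.9949146196,
                        n_heavy_isotopes = 4L,
                        spacer_length = 7.7) {
  delta <- n_heavy_isotopes * (MASS_H2 - MASS_H1)
  structure(list(name = name,
                 bridge_mass_light = bridge_mass_light,
                 bridge_mass_heavy = bridge_mass_light + delta,
                 isotope_delta = delta,
                 spacer_length = spacer_length),
            class = "xl_linker")
}

#' Tryptic digestion of a protein sequence
#'
#' Cleaves C-terminal to K or R except when the next residue is P; emits all
#' peptides with up to `max_missed` internal (missed) cleavage sites, with
#' monoisotopic masses.
#'
#' @param sequence one-letter amino-acid string (20 canonical residues).
#' @param max_missed maximum missed cleavages (default 3: a cross-linked
#'   lysine itself blocks cleavage).
#' @param id parent protein id recorded on each peptide.
#' @return data.frame with `parent`, `start`, `end`, `sequence`, `missed`,
#'   `mass`.
#' @export
digest <- function(sequence, max_missed = 3L, id = "protein") {
  sequence <- toupper(sequence)
  res <- strsplit(sequence, "")[[1]]
  if (length(res) == 0L) stop("empty sequence")
  bad <- setdiff(unique(res), names(AA_MONO))
  if (length(bad)) stop("invalid residue letter(s): ", paste(bad, collapse = ""))
  n <- length(res)
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & res[pmin(cut_after + 1L, n)] != "P" |
                           cut_after == n]
  boundaries <- c(0L, cut_after, if (!n %in% cut_after) n)
  boundaries <- sort(unique(boundaries))
  starts <- boundaries[-length(boundaries)] + 1L
  ends <- boundaries[-1L]
  out <- list()
  nfrag <- length(starts)
  for (i in seq_len(nfrag)) {
    for (j in i:min(nfrag, i + max_missed)) {
      s <- starts[i]; e <- ends[j]
      seqs <- substr(sequence, s, e)
      out[[length(out) + 1L]] <- data.frame(
        parent = id, start = s, end = e, sequence = seqs,
        missed = j - i,
        mass = peptide_mass(seqs), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Monoisotopic peptide mass
#' @param sequence peptide string.
#' @return Da.
#' @export
peptide_mass <- function(sequence) {
  vapply(strsplit(toupper(sequence), ""), function(r) {
    m <- AA_MONO[r]
    if (anyNA(m)) stop("invalid residue in peptide ", sequence)
    sum(m) + MASS_WATER
  }, numeric(1))
}

#' Digest every sequence of a FASTA file (or named character vector)
#' @param fasta path to a FASTA file, or a named character vector.
#' @param max_missed maximum missed cleavages.
#' @return combined peptide data.frame (see [digest()]).
#' @export
digest_fasta <- function(fasta, max_missed = 3L) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    x <- Biostrings::readAAStringSet(fasta)
    stats::setNames(as.character(x), sub("\\s.*", "", names(x)))
  } else fasta
  do.call(rbind, lapply(names(seqs), function(id)
    digest(seqs[[id]], max_missed = max_missed, id = id)))
}

# linkable lysine positions within a peptide (peptide-local indices).
# A C-terminal K is not a valid link site (it would have been cleaved);
# position 1 of a protein N-terminal peptide is linkable through the N-terminus.
link_sites <- function(pep_seq, pep_start, allow_nterm = TRUE) {
  res <- strsplit(pep_seq, "")[[1]]
  sites <- which(res == "K")
  sites <- sites[sites < length(res)]
  if (allow_nterm && pep_start == 1L && !(1L %in% sites)) sites <- c(1L, sites)
  sites
}

#' Enumerate cross-linked candidate pairs matching a precursor mass
#'
#' Returns all (alpha, beta, site, site) combinations whose summed peptide
#' masses plus the bridge mass (d0 or d4 form) fall within `ms1_tol_ppm` of
#' the precursor neutral mass. Both peptides must have at least `min_length`
#' residues and a linkable lysine (or be a protein N-terminal peptide).
#'
#' @param peptides data.frame from [digest_fasta()].
#' @param linker `xl_linker`.
#' @param precursor_mass neutral monoisotopic mass, Da.
#' @param ms1_tol_ppm MS1 tolerance in parts per million.
#' @param min_length minimum peptide length (default 5).
#' @return data.frame of candidates (possibly 0 rows) with columns
#'   `alpha_idx`, `beta_idx`, `alpha_site`, `beta_site`, `form`, `mass_error_ppm`.
#' @export
enumerate_candidates <- function(peptides, linker, precursor_mass,
                                 ms1_tol_ppm = 1, min_length = 5L) {
  idx <- xl_peptide_index(peptides, min_length)
  enumerate_from_index(idx, linker, precursor_mass, ms1_tol_ppm)
}

# linkable-peptide index: filter once, compute link sites once
xl_peptide_index <- function(peptides, min_length = 5L) {
  peptides <- peptides[nchar(peptides$sequence) >= min_length, , drop = FALSE]
  if (nrow(peptides)) {
    sites <- lapply(seq_len(nrow(peptides)), function(i)
      link_sites(peptides$sequence[i], peptides$start[i]))
    keep <- lengths(sites) > 0L
    peptides <- peptides[keep, , drop = FALSE]
    sites <- sites[keep]
  } else sites <- list()
  rownames(peptides) <- NULL
  list(peptides = peptides, sites = sites)
}

enumerate_from_index <- function(idx, linker, precursor_mass,
                                 ms1_tol_ppm = 1) {
  peptides <- idx$peptides
  if (nrow(peptides) == 0L) return(empty_candidates())
  m <- peptides$mass
  ord <- order(m); ms <- m[ord]
  out <- list()
  for (form in c("d0", "d4")) {
    bridge <- if (form == "d0") linker$bridge_mass_light
              else linker$bridge_mass_heavy
    target <- precursor_mass - bridge
    tol <- ms1_tol_ppm * 1e-6 * precursor_mass
    for (i in seq_along(m)) {
      lo <- findInterval(target - m[i] - tol, ms) + 1L
      hi <- findInterval(target - m[i] + tol, ms)
      if (hi < lo) next
      for (j in ord[lo:hi]) {
        if (j < i) next  # unordered pairs once
        for (sa in idx$sites[[i]]) for (sb in idx$sites[[j]]) {
          out[[length(out) + 1L]] <- list(i = i, j = j, sa = sa, sb = sb,
                                          form = form, bridge = bridge)
        }
      }
    }
  }
  if (!length(out)) return(empty_candidates())
  ii <- vapply(out, `[[`, 0L, "i"); jj <- vapply(out, `[[`, 0L, "j")
  data.frame(
    alpha_idx = as.character(ii), beta_idx = as.character(jj),
    alpha_parent = peptides$parent[ii], beta_parent = peptides$parent[jj],
    alpha_seq = peptides$sequence[ii], beta_seq = peptides$sequence[jj],
    alpha_start = peptides$start[ii], beta_start = peptides$start[jj],
    alpha_site = vapply(out, `[[`, 0L, "sa"),
    beta_site = vapply(out, `[[`, 0L, "sb"),
    form = vapply(out, `[[`, "", "form"),
    mass_error_ppm = (m[ii] + m[jj] + vapply(out, `[[`, 0, "bridge") -
                        precursor_mass) / precursor_mass * 1e6,
    stringsAsFactors = FALSE)
}

empty_candidates <- function() {
  data.frame(alpha_idx = character(), beta_idx = character(),
             alpha_parent = character(), beta_parent = character(),
             alpha_seq = character(), beta_seq = character(),
             alpha_start = integer(), beta_start = integer(),
             alpha_site = integer(), beta_site = integer(),
             form = character(), mass_error_ppm = numeric(),
             stringsAsFactors = FALSE)
}

#' Pair isotope-coded precursor doublets
#'
#' Pairs deisotoped precursor features of equal charge (z in 3..6),
#' co-eluting within `rt_window`, whose neutral-mass difference matches the
#' linker's isotope delta within `ppm` (of the neutral mass, inclusive at
#' the boundary).
#'
#' @param features data.frame with `mz`, `charge`, `rt` (retention index).
#' @param delta expected neutral-mass difference, Da (default the BS2G
#'   d4 - d0 shift).
#' @param ppm tolerance, parts per million of the neutral mass.
#' @param rt_window maximum co-elution separation.
#' @param charge_range allowed charges.
#' @return data.frame with `light`, `heavy` row indices into `features`.
#' @export
detect_isotope_doublets <- function(features, delta = linker_bs2g()$isotope_delta,
                                    ppm = 10, rt_window = 1,
                                    charge_range = 3:6) {
  neutral <- (features$mz - MASS_PROTON) * features$charge
  pairs <- list()
  idx <- which(features$charge %in% charge_range)
  for (i in idx) for (j in idx) {
    if (i == j) next
    dm <- neutral[j] - neutral[i]
    if (dm <= 0) next
    if (features$charge[i] != features$charge[j]) next
    if (abs(features$rt[i] - features$rt[j]) > rt_window) next
    if (abs(dm - delta) <= ppm * 1e-6 * neutral[i])
      pairs[[length(pairs) + 1L]] <- data.frame(light = i, heavy = j)
  }
  if (!length(pairs)) return(data.frame(light = integer(), heavy = integer()))
  do.call(rbind, pairs)
}

#' Theoretical b/y fragment ions of a cross-linked peptide
#'
#' The cross-linked residue carries the partner peptide plus bridge as a
#' fixed mass shift. Ions are generated for both peptides at product charges
#' 1 to `max_charge`.
#'
#' @param alpha_seq,beta_seq peptide sequences.
#' @param alpha_site,beta_site linked residue positions (1-based, local).
#' @param bridge_mass bridge mass of the observed isotope form, Da.
#' @param max_charge highest product-ion charge.
#' @return data.frame with `peptide` ("alpha"/"beta"), `ion`, `charge`, `mz`.
#' @export
fragment_ions <- function(alpha_seq, beta_seq, alpha_site, beta_site,
                          bridge_mass, max_charge = 2L) {
  one <- function(seqs, site, partner_mass, who) {
    mres <- AA_MONO[strsplit(seqs, "")[[1]]]
    shift <- partner_mass + bridge_mass
    n <- length(mres)
    i <- seq_len(n - 1L)
    pre <- cumsum(mres)[i]
    b_neutral <- pre + ifelse(site <= i, shift, 0)
    y_neutral <- (sum(mres) - pre) + MASS_WATER + ifelse(site > i, shift, 0)
    z <- rep(seq_len(max_charge), each = length(i))
    data.frame(
      peptide = who,
      ion = c(sprintf("b%d", rep(i, max_charge)),
              sprintf("y%d", rep(n - i, max_charge))),
      charge = c(z, z),
      mz = c((rep(b_neutral, max_charge) + z * MASS_PROTON) / z,
             (rep(y_neutral, max_charge) + z * MASS_PROTON) / z),
      stringsAsFactors = FALSE)
  }
  rbind(one(alpha_seq, alpha_site, peptide_mass(beta_seq), "alpha"),
        one(beta_seq, beta_site, peptide_mass(alpha_seq), "beta"))
}

#' Score a cross-link candidate against a spectrum
#'
#' Score = sum over matched theoretical b/y ions of
#' `1 + log10(relative intensity)`, where relative intensity is the peak
#' intensity divided by the maximum intensity in the spectrum; each
#' theoretical ion matches at most the closest peak within `ms2_tol_ppm`.
#'
#' @param candidate one row of [enumerate_candidates()] output (or a list
#'   with the same fields).
#' @param peaks data.frame with `mz`, `intensity`.
#' @param linker `xl_linker`.
#' @param ms2_tol_ppm fragment tolerance, ppm.
#' @param max_charge highest product-ion charge considered.
#' @return numeric score (0 for an empty spectrum).
#' @export
score_match <- function(candidate, peaks, linker, ms2_tol_ppm = 0.1,
                        max_charge = 2L) {
  if (is.null(peaks) || nrow(peaks) == 0L) return(0)
  bridge <- if (candidate$form == "d0") linker$bridge_mass_light
            else linker$bridge_mass_heavy
  ions <- fragment_ions(candidate$alpha_seq, candidate$beta_seq,
                        candidate$alpha_site, candidate$beta_site,
                        bridge, max_charge = max_charge)
  score_ions(ions$mz, peaks, ms2_tol_ppm)
}

# vectorized matcher: each theoretical m/z matches the most intense peak
# within tolerance; contribution 1 + log10(relative intensity)
score_ions <- function(ion_mz, peaks, ms2_tol_ppm) {
  if (nrow(peaks) == 0L || length(ion_mz) == 0L) return(0)
  ord <- order(peaks$mz)
  pmz <- peaks$mz[ord]
  rel <- (peaks$intensity / max(peaks$intensity))[ord]
  tol <- ms2_tol_ppm * 1e-6 * ion_mz
  lo <- findInterval(ion_mz - tol, pmz) + 1L
  hi <- findInterval(ion_mz + tol, pmz)
  score <- 0
  for (k in seq_along(ion_mz)) {
    if (hi[k] < lo[k]) next
    score <- score + 1 + log10(max(rel[lo[k]:hi[k]]))
  }
  score
}

#' Decoy database by sequence reversal
#' @param seqs named character vector of protein sequences.
#' @return named character vector, ids prefixed `decoy_`.
#' @export
make_decoys <- function(seqs) {
  rev1 <- vapply(seqs, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), "")
  stats::setNames(rev1, paste0("decoy_", names(seqs)))
}

#' Decoy-based q-values for scored matches
#'
#' At each score threshold the FDR estimate is
#' `(# decoy matches >= threshold) / (# target matches >= threshold)`; the
#' q-value of a match is the minimum FDR at or below its score rank.
#'
#' @param scores numeric match scores.
#' @param decoy logical decoy flags.
#' @return numeric q-values (same order as `scores`).
#' @export
estimate_fdr <- function(scores, decoy) {
  stopifnot(length(scores) == length(decoy))
  n <- length(scores)
  if (n == 0L) return(numeric(0))
  ord <- order(scores, decreasing = TRUE)
  dec_cum <- cumsum(decoy[ord])
  tgt_cum <- cumsum(!decoy[ord])
  fdr <- ifelse(tgt_cum == 0, 1, dec_cum / tgt_cum)
  q_sorted <- rev(cummin(rev(pmin(fdr, 1))))
  q <- numeric(n)
  q[ord] <- q_sorted
  q
}

#' Search MS/MS spectra for isotope-coded cross-links
#'
#' For each spectrum: enumerate target+decoy candidates at the precursor
#' mass, score them, and keep the best candidate. Decoy-based q-values are
#' computed across spectra, repeat observations of the same residue pair are
#' counted, and matches with `q <= fdr` and `times_observed > min_obs - 1`
#' are flagged accepted.
#'
#' @param spectra list of spectra, each a list with `precursor_mass` (neutral
#'   Da), `charge`, and `peaks` (data.frame `mz`, `intensity`).
#' @param sequences named character vector of target protein sequences.
#' @param linker `xl_linker`.
#' @param ms1_tol_ppm,ms2_tol_ppm tolerances.
#' @param fdr q-value acceptance threshold (default 0.05).
#' @param min_obs minimum times a residue pair must be observed (default 3,
#'   i.e. "more than 2 times").
#' @param min_length minimum peptide length.
#' @param max_missed missed cleavages for digestion.
#' @return data.frame of best-per-spectrum matches with q-values and an
#'   `accepted` flag.
#' @export
xl_search <- function(spectra, sequences, linker = linker_bs2g(),
                      ms1_tol_ppm = 1, ms2_tol_ppm = 0.1, fdr = 0.05,
                      min_obs = 3L, min_length = 5L, max_missed = 3L) {
  all_seqs <- c(sequences, make_decoys(sequences))
  peptides <- digest_fasta(all_seqs, max_missed = max_missed)
  index <- xl_peptide_index(peptides, min_length)
  hits <- list()
  for (si in seq_along(spectra)) {
    sp <- spectra[[si]]
    cand <- enumerate_from_index(index, linker, sp$precursor_mass,
                                 ms1_tol_ppm = ms1_tol_ppm)
    if (nrow(cand) == 0L) next
    sc <- vapply(seq_len(nrow(cand)), function(ci)
      score_match(cand[ci, ], sp$peaks, linker, ms2_tol_ppm = ms2_tol_ppm,
                  max_charge = max(1L, sp$charge - 1L)),
      numeric(1))
    best <- which.max(sc)
    h <- cand[best, ]
    h$spectrum <- si
    h$charge <- sp$charge
    h$score <- sc[best]
    h$decoy <- grepl("^decoy_", h$alpha_parent) |
      grepl("^decoy_", h$beta_parent)
    hits[[length(hits) + 1L]] <- h
  }
  if (!length(hits)) {
    return(data.frame())
  }
  hits <- do.call(rbind, hits)
  rownames(hits) <- NULL
  hits$alpha_pos <- hits$alpha_start + hits$alpha_site - 1L
  hits$beta_pos <- hits$beta_start + hits$beta_site - 1L
  hits$q <- estimate_fdr(hits$score, hits$decoy)
  pair_id <- apply(hits[, c("alpha_parent", "alpha_pos", "beta_parent",
                            "beta_pos")], 1L, function(r) {
    a <- paste(r[1], r[2], sep = ":"); b <- paste(r[3], r[4], sep = ":")
    paste(sort(c(a, b)), collapse = "--")
  })
  hits$pair_id <- pair_id
  hits$times_observed <- as.integer(table(pair_id)[pair_id])
  hits$accepted <- !hits$decoy & hits$q <= fdr & hits$times_observed >= min_obs
  hits
}

#' Convert accepted cross-links to flat-bottom distance restraints
#'
#' Each accepted lysine-lysine link becomes a restraint between the two NZ
#' atoms with bounds `[0, upper_bound]`. Links whose residues are missing
#' from the coordinates are dropped with a warning.
#'
#' @param matches accepted rows of [xl_search()] output (or a data.frame
#'   with `alpha_parent`, `alpha_pos`, `beta_parent`, `beta_pos`).
#' @param chain_map named character vector mapping protein ids to
#'   `"body:chain"` strings (body "A" or "B").
#' @param bodies list with elements `A` and `B` (`rigid_body`).
#' @param upper_bound flat-bottom upper bound, Angstrom (default 20: 7.7 A
#'   spacer plus lysine side-chain flexibility).
#' @param atom linked atom name (default `"NZ"`).
#' @return list of `distance_restraint` objects.
#' @export
crosslinks_to_restraints <- function(matches, chain_map, bodies,
                                     upper_bound = 20, atom = "NZ") {
  out <- list()
  for (i in seq_len(nrow(matches))) {
    m <- matches[i, ]
    mk_site <- function(parent, pos) {
      if (!parent %in% names(chain_map)) stop("unmappable protein id: ", parent)
      bc <- strsplit(chain_map[[parent]], ":")[[1]]
      list(body = bc[1], kind = "atom", chain = bc[2],
           resnum = as.integer(pos), atom = atom)
    }
    sa <- mk_site(m$alpha_parent, m$alpha_pos)
    sb <- mk_site(m$beta_parent, m$beta_pos)
    resolved <- tryCatch({
      atom_position(bodies[[sa$body]], sa$chain, sa$resnum, sa$atom)
      atom_position(bodies[[sb$body]], sb$chain, sb$resnum, sb$atom)
      TRUE
    }, error = function(e) FALSE)
    if (!resolved) {
      warning(sprintf("cross-link %s:%d -- %s:%d unresolved in coordinates; dropped",
                      m$alpha_parent, m$alpha_pos, m$beta_parent, m$beta_pos))
      next
    }
    out[[length(out) + 1L]] <- distance_restraint(
      site_a = sa, site_b = sb, target = NA_real_, lower = 0,
      upper = upper_bound, source = "XLMS",
      label = sprintf("%s:%d--%s:%d", m$alpha_parent, m$alpha_pos,
                      m$beta_parent, m$beta_pos))
  }
  out
}

# ---- MGF format ----------------------------------------------------------

#' Read an MGF peak-list file
#' @param path MGF file.
#' @return list of spectra: `title`, `precursor_mz`, `charge`,
#'   `precursor_mass` (neutral), `rt`, `peaks`.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends)) stop("malformed MGF: unbalanced blocks")
  lapply(seq_along(begins), function(i) {
    blk <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    kv <- grepl("=", blk, fixed = TRUE)
    hdr <- blk[kv]
    get <- function(key) {
      m <- hdr[startsWith(hdr, paste0(key, "="))]
      if (!length(m)) return(NA_character_)
      sub(paste0(key, "="), "", m[1], fixed = TRUE)
    }
    pk <- blk[!kv & nzchar(blk)]
    mat <- do.call(rbind, lapply(strsplit(pk, "[ \t]+"), as.numeric))
    charge <- as.integer(sub("\\+$", "", get("CHARGE")))
    pmz <- as.numeric(strsplit(get("PEPMASS"), " ")[[1]][1])
    list(title = get("TITLE"), precursor_mz = pmz, charge = charge,
         precursor_mass = (pmz - MASS_PROTON) * charge,
         rt = suppressWarnings(as.numeric(get("RTINSECONDS"))),
         peaks = if (length(pk)) data.frame(mz = mat[, 1], intensity = mat[, 2])
                 else data.frame(mz = numeric(), intensity = numeric()))
  })
}

#' Write spectra to an MGF file
#' @param spectra list as returned by [read_mgf()].
#' @param path output file.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=%s",
                       if (is.null(sp$title) || is.na(sp$title))
                         sprintf("spectrum_%d", i) else sp$title), con)
    pmz <- if (!is.null(sp$precursor_mz)) sp$precursor_mz
           else sp$precursor_mass / sp$charge + MASS_PROTON
    writeLines(sprintf("PEPMASS=%.6f", pmz), con)
    writeLines(sprintf("CHARGE=%d+", sp$charge), con)
    if (!is.null(sp$rt) && !is.na(sp$rt))
      writeLines(sprintf("RTINSECONDS=%.2f", sp$rt), con)
    if (nrow(sp$peaks))
      writeLines(sprintf("%.6f %.4f", sp$peaks$mz, sp$peaks$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Write sequences to a FASTA file
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(seqs[[nm]], con)
  }
  invisible(path)
}
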