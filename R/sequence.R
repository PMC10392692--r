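# Sequence-level titration model: per-site Henderson-Hasselbalch charges,
# net charge versus pH, isoelectric point and region charges.

AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a protein sequence
#'
#' A light container for a one-letter amino-acid sequence with flags for
#' free (titratable) termini.  The alphabet is restricted to the 20
#' standard residues.
#'
#' @param residues Character scalar (one-letter codes, case-insensitive) or
#'   character vector of single codes.
#' @param name Label for the sequence.
#' @param has_free_nterm,has_free_cterm Logical; whether the terminal amine
#'   and carboxyl groups are free to titrate.  A grafted or capped terminus
#'   should be \code{FALSE}.
#' @return An object of class \code{protein_sequence}: a character vector of
#'   residues with attributes \code{name}, \code{has_free_nterm},
#'   \code{has_free_cterm}.
#' @examples
#' protein_sequence("MDVFMK", name = "toy")
#' @export
protein_sequence <- function(residues, name = "seq",
                             has_free_nterm = TRUE, has_free_cterm = TRUE) {
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "")[[1]]
  residues <- toupper(as.character(residues))
  if (length(residues) < 1L)
    stop("sequence must contain at least one residue")
  bad <- setdiff(unique(residues), AA_CODES)
  if (length(bad) > 0L)
    stop("invalid amino-acid code(s): ", paste(bad, collapse = ", "))
  structure(residues,
            name = name,
            has_free_nterm = isTRUE(has_free_nterm),
            has_free_cterm = isTRUE(has_free_cterm),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("protein_sequence '%s': %d residues\n", attr(x, "name"),
              length(x)))
  cat(paste(x, collapse = ""), "\n")
  cat(sprintf("free N-terminus: %s, free C-terminus: %s\n",
              attr(x, "has_free_nterm"), attr(x, "has_free_cterm")))
  invisible(x)
}

#' Read the first record of a FASTA file as a protein sequence
#'
#' @param path Path to a FASTA file.
#' @param has_free_nterm,has_free_cterm Passed to
#'   \code{\link{protein_sequence}}.
#' @return A \code{\link{protein_sequence}} (first record only, uppercased).
#' @examples
#' fa <- system.file("extdata", "asyn.fasta", package = "saltsyn")
#' length(read_fasta(fa))  # 140
#' @export
read_fasta <- function(path, has_free_nterm = TRUE, has_free_cterm = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                             forceDNAtolower = FALSE)
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  protein_sequence(as.character(recs[[1]]),
                   name = attr(recs[[1]], "name"),
                   has_free_nterm = has_free_nterm,
                   has_free_cterm = has_free_cterm)
}

#' Packaged alpha-synuclein sequences
#'
#' Convenience loaders for the packaged fixtures: the 140-residue human
#' alpha-synuclein sequence and its C-terminal tail (residues 101-140).
#' The tail is loaded without a free N-terminal amine by default because in
#' the simulated system it is grafted to the surface via its N-terminus.
#'
#' @return A \code{\link{protein_sequence}}.
#' @export
asyn_sequence <- function() {
  read_fasta(system.file("extdata", "asyn.fasta", package = "saltsyn"))
}

#' @rdname asyn_sequence
#' @param grafted Logical; if \code{TRUE} (default) the N-terminus is not
#'   titratable (anchored), as for the surface-grafted tails.
#' @export
asyn_ctail <- function(grafted = TRUE) {
  read_fasta(system.file("extdata", "asyn_ctail.fasta", package = "saltsyn"),
             has_free_nterm = !grafted)
}

#' Default intrinsic pKa set
#'
#' Intrinsic (model-compound) pKa values for the titratable side chains and
#' the free termini, as used throughout the package: D 4.0, E 4.4, H 6.3,
#' Y 9.6, K 10.4, R 12.0, C 10.8, N-terminus 7.5, C-terminus 3.6.  These
#' are the common coarse-grained model values; any named numeric vector
#' with the same names can be supplied wherever a \code{pka_set} argument
#' is accepted, e.g. a measured per-residue-type table.
#'
#' @return Named numeric vector with entries D, E, H, Y, K, R, C, Nterm,
#'   Cterm (pH units).
#' @export
default_pka_set <- function() {
  c(D = 4.0, E = 4.4, H = 6.3, Y = 9.6, K = 10.4, R = 12.0, C = 10.8,
    Nterm = 7.5, Cterm = 3.6)
}

#' Read a pKa set from a plain-text key-value file
#'
#' The file holds one \code{key: value} (or \code{key = value}) pair per
#' line; keys are the residue codes D, E, H, Y, K, R, C plus \code{Nterm}
#' and \code{Cterm}.  Missing keys fall back to \code{default_pka_set()}.
#'
#' @param path Path to the file.
#' @return Named numeric vector as \code{\link{default_pka_set}}.
#' @export
read_pka_set <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- default_pka_set()
  for (ln in lines) {
    kv <- strsplit(ln, "[:=]")[[1]]
    if (length(kv) != 2L) stop("malformed pKa line: ", ln)
    key <- trimws(kv[1]); val <- as.numeric(trimws(kv[2]))
    if (!key %in% names(out)) stop("unknown pKa key: ", key)
    if (!is.finite(val) || val <= 0 || val >= 14)
      stop("pKa out of (0, 14) for ", key)
    out[key] <- val
  }
  out
}

ACID_KEYS <- c("D", "E", "Y", "C", "Cterm")
BASE_KEYS <- c("H", "K", "R", "Nterm")

#' Enumerate titratable sites of a sequence
#'
#' One site per D, E, H, Y, K, R or C residue, plus the free termini when
#' flagged on the sequence.  Positions are 1-based residue indices; the
#' N-terminal amine is reported at position 0 and the C-terminal carboxyl
#' at \code{length(seq) + 1}.
#'
#' @param seq A \code{\link{protein_sequence}}.
#' @param pka_set Named pKa vector, see \code{\link{default_pka_set}}.
#' @return A data.frame with columns \code{position}, \code{residue} (the
#'   site key), \code{kind} ("acid" or "base"), \code{pKa},
#'   \code{charge_protonated}, \code{charge_deprotonated}.
#' @export
titratable_sites <- function(seq, pka_set = default_pka_set()) {
  stopifnot(inherits(seq, "protein_sequence"))
  need <- c(ACID_KEYS, BASE_KEYS)
  if (!all(need %in% names(pka_set)))
    stop("pka_set must name all of: ", paste(need, collapse = ", "))
  if (any(pka_set <= 0 | pka_set >= 14))
    stop("all pKa values must lie in (0, 14)")
  pos <- which(seq %in% c("D", "E", "H", "Y", "K", "R", "C"))
  res <- as.character(seq[pos])
  if (attr(seq, "has_free_nterm")) { pos <- c(0L, pos); res <- c("Nterm", res) }
  if (attr(seq, "has_free_cterm")) {
    pos <- c(pos, length(seq) + 1L); res <- c(res, "Cterm")
  }
  kind <- ifelse(res %in% ACID_KEYS, "acid", "base")
  out <- data.frame(position = as.integer(pos), residue = res, kind = kind,
                    pKa = unname(pka_set[res]),
                    charge_protonated = ifelse(kind == "acid", 0, 1),
                    charge_deprotonated = ifelse(kind == "acid", -1, 0),
                    stringsAsFactors = FALSE)
  out[order(out$position), , drop = FALSE]
}

#' Mean charge of a titratable site at a given pH
#'
#' Henderson-Hasselbalch occupancy: an acid contributes
#' \eqn{-1/(1 + 10^{pKa - pH})} and a base \eqn{+1/(1 + 10^{pH - pKa})}.
#'
#' @param kind "acid" or "base" (vectorised).
#' @param pKa Intrinsic pKa (pH units).
#' @param pH Solution pH.
#' @return Mean charge in units of e.
#' @examples
#' site_mean_charge("acid", 4.0, 4.0)   # -0.5
#' @export
site_mean_charge <- function(kind, pKa, pH) {
  ifelse(kind == "acid",
         -1 / (1 + 10^(pKa - pH)),
         +1 / (1 + 10^(pH - pKa)))
}

#' Net charge of a sequence at a given pH
#'
#' Sum of Henderson-Hasselbalch mean charges over all titratable sites.
#' Strictly decreasing in pH whenever the sequence has at least one site.
#'
#' @inheritParams titratable_sites
#' @param pH Solution pH (vectorised).
#' @return Net charge in e.
#' @examples
#' net_charge(asyn_sequence(), 5.5)  # < 0
#' @export
net_charge <- function(seq, pH, pka_set = default_pka_set()) {
  sites <- titratable_sites(seq, pka_set)
  vapply(pH, function(p) {
    sum(site_mean_charge(sites$kind, sites$pKa, p))
  }, numeric(1))
}

#' Isoelectric point
#'
#' The unique pH in (0, 14) at which the mean net charge vanishes, found by
#' bisection to |q| < 1e-6 e.  Requires at least one acid and one base site
#' (otherwise the net charge never changes sign and the pI is undefined).
#'
#' @inheritParams titratable_sites
#' @return pH units (numeric scalar).
#' @examples
#' isoelectric_point(asyn_sequence())  # about 4.6
#' @export
isoelectric_point <- function(seq, pka_set = default_pka_set()) {
  sites <- titratable_sites(seq, pka_set)
  if (!any(sites$kind == "acid") || !any(sites$kind == "base"))
    stop("undefined pI: sequence needs at least one acid and one base site")
  f <- function(p) net_charge(seq, p, pka_set)
  lo <- 1e-6; hi <- 14 - 1e-6
  qlo <- f(lo); qhi <- f(hi)
  if (qlo <= 0 || qhi >= 0)
    stop("undefined pI: net charge does not change sign on (0, 14)")
  # bisection on the strictly decreasing net-charge curve
  repeat {
    mid <- (lo + hi) / 2
    q <- f(mid)
    if (abs(q) < 1e-6 || (hi - lo) < 1e-12) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Charge profile of a sequence at one pH
#'
#' Per-site mean charges, net charge and summed mean charge over residue
#' regions.  The default regions are the classical alpha-synuclein split:
#' N-terminal 1-60, NAC 61-95 and C-terminal tail 101-140.
#'
#' @inheritParams titratable_sites
#' @param pH Solution pH.
#' @param regions Named list of length-2 integer vectors
#'   \code{c(first, last)} (1-based, inclusive).  Terminal sites (positions
#'   0 and length+1) count toward a region containing residue 1 or
#'   length(seq), respectively.
#' @return An object of class \code{charge_profile}: list with \code{pH},
#'   \code{sites} (data.frame with \code{charge} column), \code{net_charge}
#'   and \code{region_charges} (named numeric).
#' @export
charge_profile <- function(seq, pH, pka_set = default_pka_set(),
                           regions = list(nterm = c(1, 60),
                                          nac = c(61, 95),
                                          ctail = c(101, 140))) {
  sites <- titratable_sites(seq, pka_set)
  sites$charge <- site_mean_charge(sites$kind, sites$pKa, pH)
  n <- length(seq)
  # map terminal pseudo-positions onto the terminal residues for regions
  pos_eff <- pmin(pmax(sites$position, 1L), n)
  rc <- vapply(regions, function(r) {
    sum(sites$charge[pos_eff >= r[1] & pos_eff <= r[2]])
  }, numeric(1))
  structure(list(pH = pH, sites = sites, net_charge = sum(sites$charge),
                 region_charges = rc, name = attr(seq, "name")),
            class = "charge_profile")
}

#' @export
print.charge_profile <- function(x, ...) {
  cat(sprintf("charge_profile of '%s' at pH %.2f\n", x$name, x$pH))
  cat(sprintf("  net charge: %+.3f e over %d titratable sites\n",
              x$net_charge, nrow(x$sites)))
  for (nm in names(x$region_charges))
    cat(sprintf("  region %-8s %+.3f e\n", nm, x$region_charges[[nm]]))
  invisible(x)
}

#' Net-charge-versus-pH table
#'
#' Tabulates net charge and region charges on a pH grid, optionally writing
#' a TSV (columns: pH, net_charge, one column per region).
#'
#' @inheritParams charge_profile
#' @param pH_grid Numeric vector of pH values.
#' @param file Optional path of a TSV to write.
#' @return data.frame (invisibly if \code{file} given).
#' @export
charge_table <- function(seq, pH_grid = seq(2, 12, by = 0.1),
                         pka_set = default_pka_set(),
                         regions = list(nterm = c(1, 60),
                                        nac = c(61, 95),
                                        ctail = c(101, 140)),
                         file = NULL) {
  rows <- lapply(pH_grid, function(p) {
    cp <- charge_profile(seq, p, pka_set, regions)
    c(pH = p, net_charge = cp$net_charge, cp$region_charges)
  })
  out <- as.data.frame(do.call(rbind, rows))
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' @export
plot.charge_profile <- function(x, ...) {
  s <- x$sites
  graphics::plot(s$position, s$charge, type = "h",
                 col = ifelse(s$kind == "acid", "firebrick", "steelblue"),
                 xlab = "residue position", ylab = "mean charge (e)",
                 main = sprintf("%s, pH %.2f", x$name, x$pH), ...)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}
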