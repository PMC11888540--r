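#' Construct a chemical-shift table
#'
#' Per-residue Calpha and Cbeta shifts in ppm. Glycine has no Cbeta;
#' use `NA`.
#'
#' @param resid Residue indices (monotone increasing).
#' @param resname Residue 3-letter names.
#' @param ca,cb Calpha / Cbeta shifts (ppm); `cb` may be `NA` (glycine).
#' @return data.frame of class `shift_table`.
#' @export
shift_table <- function(resid, resname, ca, cb) {
  resid <- as.integer(resid)
  if (is.unsorted(resid, strictly = TRUE))
    stop("residue indices must be strictly increasing")
  structure(data.frame(resid = resid, resname = toupper(resname),
                       ca = ca, cb = cb, stringsAsFactors = FALSE),
            class = c("shift_table", "data.frame"))
}

#' Read a chemical-shift table from a TSV file
#'
#' Whitespace-separated columns: residue index, residue name, Calpha
#' shift, Cbeta shift (`NA` or `-` for glycine). Lines starting with `#`
#' are comments.
#'
#' @param path File path.
#' @return A [shift_table()].
#' @export
read_shift_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#",
                          na.strings = c("NA", "-"), stringsAsFactors = FALSE)
  names(df)[1:4] <- c("resid", "resname", "ca", "cb")
  shift_table(df$resid, df$resname, df$ca, df$cb)
}

#' Load the bundled random-coil reference shifts
#'
#' A small per-residue-type table of approximate random-coil Calpha and
#' Cbeta shifts shipped for testing and examples. It is synthetic in the
#' sense of being a coarse, non-authoritative composite: for real
#' analyses supply a sequence- and condition-corrected reference table.
#'
#' @param sequence Optional 1-letter sequence; if given, the per-type
#'   table is expanded to a per-residue [shift_table()].
#' @return data.frame (per residue type), or a [shift_table()] if
#'   `sequence` is given.
#' @export
random_coil_shifts <- function(sequence = NULL) {
  path <- system.file("extdata", "random_coil_ca_cb_synthetic.tsv",
                      package = "ffbalance")
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           na.strings = "NA", stringsAsFactors = FALSE)
  if (is.null(sequence)) return(tab)
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  res3 <- .AA3[letters1]
  if (anyNA(res3)) stop("unknown residue letter(s): ",
                        paste(letters1[is.na(res3)], collapse = ", "))
  i <- match(res3, tab$resname)
  shift_table(seq_along(res3), res3, tab$ca[i], tab$cb[i])
}

#' Secondary chemical-shift difference per residue
#'
#' Computes `(Ca_obs - Ca_rc) - (Cb_obs - Cb_rc)` for every residue:
#' positive values indicate helical propensity, negative values beta
#' structure. For glycine (no Cbeta) the value is the Calpha secondary
#' shift alone and the row is flagged.
#'
#' @param observed,random_coil [shift_table()]s covering the same
#'   residues (matched on index and residue name).
#' @return data.frame `resid`, `resname`, `delta` (ppm), `gly_ca_only`.
#' @export
secondary_shift_delta <- function(observed, random_coil) {
  o <- observed; r <- random_coil
  i <- match(o$resid, r$resid)
  bad <- which(is.na(i) | toupper(o$resname) != toupper(r$resname[i]))
  if (length(bad))
    stop("residue mismatch between tables at observed rows: ",
         paste(sprintf("%d(%s)", o$resid[bad], o$resname[bad]), collapse = ", "))
  r <- r[i, ]
  dca <- o$ca - r$ca
  dcb <- o$cb - r$cb
  gly <- is.na(o$cb) | is.na(r$cb)
  delta <- ifelse(gly, dca, dca - dcb)
  data.frame(resid = o$resid, resname = o$resname, delta = delta,
             gly_ca_only = gly, stringsAsFactors = FALSE)
}
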