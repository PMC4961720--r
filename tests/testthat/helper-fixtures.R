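## Shared fixtures: the published sequences and the printed descriptor
## panel of the glycine scan, frozen as strings to preserve the printed
## precision of each cell.

WT <- "MAEAHQAVAFQFT"    # CPT-1a N-terminal 1-13 parent
MTP1 <- "KVSGVLFGTGLWVAL"
MTP2 <- "MAEAHQAKAFQDT"

## columns: BI, APD %, net charge, GRAVY, W-W.  Row "G11" carries a GRAVY
## misprint in the source table (see test-acceptance.R).
PRINTED_SCAN <- rbind(
  parent = c("0.42",  "61", "-1", "0.346",  "1.75"),
  G1     = c("0.53",  "53", "-1", "0.169",  "1.99"),
  G2     = c("0.49",  "53", "-1", "0.177",  "1.59"),
  G3     = c("-0.17", "61", "0",  "0.584",  "-0.26"),
  G4     = c("0.49",  "53", "-1", "0.177",  "1.59"),
  G5     = c("0",     "61", "-1", "0.561",  "1.59"),
  G6     = c("-0.07", "61", "-1", "0.585",  "1.18"),
  G7     = c("0.49",  "53", "-1", "0.177",  "1.59"),
  G8     = c("0.66",  "53", "-1", "-0.007", "1.69"),
  G9     = c("0.49",  "53", "-1", "0.177",  "1.59"),
  G10    = c("0.58",  "53", "-1", "0.1",    "2.89"),
  G11    = c("-0.07", "61", "-1", "0.546",  "1.18"),
  G12    = c("0.58",  "53", "-1", "0.1",    "2.89"),
  G13    = c("0.15",  "61", "-1", "0.369",  "1.62"),
  K8     = c("1.16",  "53", "0",  "-0.277", "2.67"),
  D12    = c("1.32",  "53", "-2", "-0.138", "4.11"),
  K8D12  = c("2.06",  "46", "-1", "-0.761", "5.03"))
colnames(PRINTED_SCAN) <- c("boman_index", "hydrophobic_ratio",
                            "net_charge", "gravy", "ww_interface")

## number of decimals a printed cell carries
printed_decimals <- function(s) {
  if (!grepl("\\.", s)) return(0L)
  nchar(sub("^-?[0-9]*\\.", "", s))
}

## a computed value agrees with a printed cell if it lies within one unit
## of the printed precision (admits truncation-toward-zero and rounding)
expect_matches_printed <- function(computed, printed) {
  p <- printed_decimals(printed)
  expect_lt(abs(computed - as.numeric(printed)), 10^(-p) + 1e-12)
}

shift_fixture <- function(name) {
  system.file("extdata", "shifts", paste0(name, ".tsv"),
              package = "pepscan", mustWork = TRUE)
}

## independent brute-force candidate enumeration: recompute every
## descriptor from the mutated string, no incremental updates, injective
## assignment of alphabet residues to position subsets
brute_force_candidates <- function(parent, positions, alphabet, maxSubs,
                                   criterion = "boman_index") {
  pr <- strsplit(parent, "")[[1]]
  rows <- list()
  for (m in seq_len(min(maxSubs, length(alphabet)))) {
    for (ps in utils::combn(sort(positions), m, simplify = FALSE)) {
      idx <- seq_along(alphabet)
      perms <- if (m == 1L) matrix(idx, ncol = 1) else {
        g <- as.matrix(expand.grid(rev(rep(list(idx), m))))[, m:1,
                                                            drop = FALSE]
        g[apply(g, 1, function(r) !anyDuplicated(r)), , drop = FALSE]
      }
      ## expand.grid varies the first factor fastest; after the reversal
      ## rows enumerate alphabet indices in odometer order (first position
      ## slowest), matching the documented generation order
      for (r in seq_len(nrow(perms))) {
        repl <- alphabet[perms[r, ]]
        if (any(repl == pr[ps])) next
        s <- pr; s[ps] <- repl; s <- paste(s, collapse = "")
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = s,
          boman_index = bomanIndex(s), gravy = gravy(s),
          ww_interface = wwInterface(s), stringsAsFactors = FALSE)
      }
    }
  }
  rows <- do.call(rbind, rows)
  rows[order(-rows[[criterion]]), , drop = FALSE]
}
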