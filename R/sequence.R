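# Sequence-level design tools: block-formula expansion, hydropathy,
# molecular mass and composition.

# Standard average residue (monomer minus water) masses, Da.
.residue_mass <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.water_mass <- 18.0153

# Kyte-Doolittle hydropathy values per residue.
.kd <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  E = -3.5, Q = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values on the Kyte-Doolittle scale, ranging from
#' -4.5 (arginine) to +4.5 (isoleucine).
#'
#' @return A tibble with columns `residue` and `kd`.
#' @export
#' @examples
#' kd_scale()
kd_scale <- function() {
  tibble(residue = names(.kd), kd = unname(.kd))
}

.check_canonical <- function(residues, what = "sequence") {
  bad <- setdiff(unique(residues), names(.residue_mass))
  if (length(bad) > 0) {
    abort(sprintf(
      "Non-canonical residue letter(s) in %s: %s",
      what, paste(bad, collapse = ", ")
    ))
  }
  invisible(residues)
}

#' Define an ELP block specification
#'
#' ELP designs are written as block formulas, e.g.
#' `"[(IPAVG)(VPGVG)2(VPGEG)(VPGVG)2(IPAVG)]12"`: parenthesised residue
#' segments with optional repeat counts, optionally grouped in square
#' brackets that repeat the whole group. Bare residue runs outside
#' parentheses are also accepted. Repeats default to 1 and nesting of
#' bracket groups is allowed.
#'
#' @param name Identifier for the design.
#' @param formula Block formula string (one-letter residue codes).
#' @return An object of class `block_spec`.
#' @seealso [expand_blocks()], [elp_library()]
#' @export
#' @examples
#' elp_block_spec("E_KI", "(VPGKG)12[(VPGVG)2(VPGIG)(VPGVG)2]12(VPGKG)12")
elp_block_spec <- function(name, formula) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  stopifnot(is.character(formula), length(formula) == 1, nzchar(formula))
  elements <- .parse_blocks(formula)
  structure(
    list(name = name, formula = formula, elements = elements),
    class = "block_spec"
  )
}

#' @export
print.block_spec <- function(x, ...) {
  cat("<block_spec>", x$name, "\n  ", x$formula, "\n", sep = "")
  invisible(x)
}

# Recursive-descent parser for the block grammar. Returns a list of
# elements; each element is list(segment = <string> | <nested elements>,
# times = <int>).
.parse_blocks <- function(formula) {
  chars <- strsplit(gsub("[[:space:]_]", "", formula), "")[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(chars)) chars[pos] else ""
  advance <- function() {
    ch <- chars[pos]
    pos <<- pos + 1L
    ch
  }
  read_int <- function() {
    digits <- character()
    while (grepl("[0-9]", peek())) digits <- c(digits, advance())
    if (length(digits) == 0) 1L else as.integer(paste(digits, collapse = ""))
  }
  read_letters <- function() {
    letters_ <- character()
    while (grepl("[A-Za-z]", peek())) letters_ <- c(letters_, advance())
    paste(letters_, collapse = "")
  }
  parse_group <- function(closer) {
    elements <- list()
    repeat {
      ch <- peek()
      if (ch == "" || ch == closer) break
      if (ch == "(") {
        advance()
        seg <- read_letters()
        if (peek() != ")") abort("Unbalanced parenthesis in block formula")
        advance()
        times <- read_int()
        .check_canonical(strsplit(seg, "")[[1]], "block formula")
        if (!nzchar(seg)) abort("Empty segment in block formula")
        elements[[length(elements) + 1]] <- list(segment = seg, times = times)
      } else if (ch == "[") {
        advance()
        inner <- parse_group("]")
        if (peek() != "]") abort("Unbalanced bracket in block formula")
        advance()
        times <- read_int()
        elements[[length(elements) + 1]] <- list(segment = inner, times = times)
      } else if (grepl("[A-Za-z]", ch)) {
        seg <- read_letters()
        .check_canonical(strsplit(seg, "")[[1]], "block formula")
        elements[[length(elements) + 1]] <- list(segment = seg, times = 1L)
      } else {
        abort(sprintf("Unexpected character '%s' in block formula", ch))
      }
    }
    elements
  }
  out <- parse_group("")
  if (pos <= length(chars)) abort("Trailing characters in block formula")
  if (length(out) == 0) abort("Empty block formula")
  out
}

.expand_elements <- function(elements) {
  pieces <- vapply(elements, function(el) {
    seg <- if (is.character(el$segment)) el$segment else .expand_elements(el$segment)
    if (el$times < 1) abort("Repeat counts must be >= 1")
    strrep(seg, el$times)
  }, character(1))
  paste(pieces, collapse = "")
}

#' Expand a block specification into a full residue sequence
#'
#' Applies repeats innermost first and concatenates segments left to right.
#'
#' @param spec A `block_spec` (see [elp_block_spec()]) or a block formula
#'   string.
#' @param name Sequence name when `spec` is a bare formula string.
#' @return An `elp_sequence` object (fields `name`, `residues`, `length`).
#' @export
#' @examples
#' expand_blocks(elp_block_spec("demo", "(VPGVG)2"))
expand_blocks <- function(spec, name = "elp") {
  if (is.character(spec)) spec <- elp_block_spec(name, spec)
  stopifnot(inherits(spec, "block_spec"))
  residues <- .expand_elements(spec$elements)
  new_elp_sequence(spec$name, residues)
}

#' Construct an ELP sequence
#'
#' @param name Identifier.
#' @param residues One-letter residue string (canonical alphabet only).
#' @return An `elp_sequence` object.
#' @export
new_elp_sequence <- function(name, residues) {
  stopifnot(is.character(residues), length(residues) == 1, nzchar(residues))
  .check_canonical(strsplit(residues, "")[[1]])
  structure(
    list(name = name, residues = residues, length = nchar(residues)),
    class = "elp_sequence"
  )
}

#' @export
print.elp_sequence <- function(x, ...) {
  shown <- if (x$length > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat("<elp_sequence> ", x$name, " (", x$length, " residues)\n  ", shown, "\n", sep = "")
  invisible(x)
}

.residues_of <- function(seq) {
  if (inherits(seq, "elp_sequence")) seq$residues else {
    stopifnot(is.character(seq), length(seq) == 1)
    .check_canonical(strsplit(seq, "")[[1]])
    seq
  }
}

#' Average molecular mass of a polypeptide
#'
#' Sum of standard average residue masses plus one water (18.0153 Da),
#' reported in kDa. Average (not monoisotopic) masses are used, matching
#' intact LC-MS determinations of ELP molecular weight.
#'
#' @param seq An `elp_sequence` or residue string.
#' @return Mass in kDa.
#' @export
#' @examples
#' average_mass("VPGVG")
average_mass <- function(seq) {
  residues <- strsplit(.residues_of(seq), "")[[1]]
  (sum(.residue_mass[residues]) + .water_mass) / 1000
}

#' Sliding-window Kyte-Doolittle hydropathy profile
#'
#' Mean Kyte-Doolittle value over a window centred at each residue. Windows
#' are truncated (not padded) at the chain ends, so edge scores average
#' fewer residues.
#'
#' @param seq An `elp_sequence` or residue string.
#' @param window Odd window width, at most the sequence length. The default
#'   of 9 is the classic choice for hydropathy plots.
#' @return A tibble of class `hydropathy_profile` with columns `position`,
#'   `residue`, `score`, and attribute `window`.
#' @export
#' @examples
#' hydropathy_profile("VPGVGVPGVG", window = 5)
hydropathy_profile <- function(seq, window = 9) {
  residues <- strsplit(.residues_of(seq), "")[[1]]
  n <- length(residues)
  if (window %% 2 == 0) abort("`window` must be odd")
  if (window > n) abort("`window` exceeds sequence length")
  half <- (window - 1) / 2
  raw <- unname(.kd[residues])
  score <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    mean(raw[lo:hi])
  }, numeric(1))
  out <- tibble(position = seq_len(n), residue = residues, score = score)
  attr(out, "window") <- window
  class(out) <- c("hydropathy_profile", class(out))
  out
}

#' Residue composition
#'
#' @param seq An `elp_sequence` or residue string.
#' @return A tibble with columns `residue`, `count`, `fraction` (fractions
#'   sum to one).
#' @export
#' @examples
#' residue_composition("VPGVG")
residue_composition <- function(seq) {
  residues <- strsplit(.residues_of(seq), "")[[1]]
  tab <- table(residues)
  tibble(
    residue = names(tab),
    count = as.integer(tab),
    fraction = as.integer(tab) / length(residues)
  ) %>% arrange(.data$residue)
}

#' The eight-member ELP design library
#'
#' Block formulas of the eight de novo ELPs studied in this package's
#' validation experiments, with their LC-MS-determined molecular weights
#' and LCST phase behavior below 37 degrees C (1 = present). Designs vary
#' the guest residue (E vs I), the cross-linking block (IPAVG, GAGAGS or
#' VPGKG) and its arrangement (multiblock vs triblock).
#'
#' @param expand If `TRUE` (default), add a `sequence` column with the
#'   expanded residue strings.
#' @return A tibble with columns `name`, `formula`, `mw_kda` (experimental),
#'   `phase_behavior` and optionally `sequence`.
#' @export
#' @examples
#' elp_library(expand = FALSE)
elp_library <- function(expand = TRUE) {
  lib <- tibble(
    name = c(
      "E_AE", "E_AE_triblock", "SE_E", "E_KE",
      "E_AI", "E_AI_triblock", "SE_I", "E_KI"
    ),
    formula = c(
      "[(IPAVG)(VPGVG)2(VPGEG)(VPGVG)2(IPAVG)]12",
      "(IPAVG)12[(VPGVG)2(VPGEG)(VPGVG)2]12(IPAVG)12",
      "[(GAGAGS)(VPGVG)2(VPGEG)(VPGVG)2(GAGAGS)]12",
      "(VPGKG)12[(VPGVG)2(VPGEG)(VPGVG)2]12(VPGKG)12",
      "[(IPAVG)(VPGVG)2(VPGIG)(VPGVG)2(IPAVG)]12",
      "(IPAVG)12[(VPGVG)2(VPGIG)(VPGVG)2]12(IPAVG)12",
      "[(GAGAGS)(VPGVG)2(VPGIG)(VPGVG)2(GAGAGS)]12",
      "(VPGKG)12[(VPGVG)2(VPGIG)(VPGVG)2]12(VPGKG)12"
    ),
    mw_kda = c(35.4, 35.4, 34.6, 35.5, 35.3, 35.3, 34.4, 35.3),
    phase_behavior = c(1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L)
  )
  if (expand) {
    lib$sequence <- vapply(
      seq_len(nrow(lib)),
      function(i) expand_blocks(elp_block_spec(lib$name[i], lib$formula[i]))$residues,
      character(1)
    )
  }
  lib
}

#' Write sequences to a FASTA file
#'
#' @param seqs A list of `elp_sequence` objects, a named character vector,
#'   or a tibble with `name` and `sequence` columns (as from
#'   [elp_library()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_elp_fasta <- function(seqs, path) {
  if (!requireNamespace("seqinr", quietly = TRUE)) {
    abort("Package 'seqinr' is required to write FASTA files")
  }
  if (is.data.frame(seqs)) {
    named <- setNames(seqs$sequence, seqs$name)
  } else if (is.character(seqs)) {
    named <- seqs
  } else {
    named <- setNames(
      vapply(seqs, function(s) s$residues, character(1)),
      vapply(seqs, function(s) s$name, character(1))
    )
  }
  seqinr::write.fasta(
    sequences = lapply(unname(named), function(s) strsplit(s, "")[[1]]),
    names = names(named), file.out = path
  )
  invisible(path)
}

#' @rdname autoplot_elptools
#' @export
autoplot.hydropathy_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Residue position",
      y = sprintf("Kyte-Doolittle hydropathy (window %d)", attr(object, "window"))
    ) +
    ggplot2::theme_minimal()
}
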