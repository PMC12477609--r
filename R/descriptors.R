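#' Parse a glycosidic-bond-angle (GBA) descriptor string
#'
#' GBA strings describe the 5'->3' glycosidic conformation (`s` = syn,
#' `a` = anti) of the core guanines of each G-tract, tracts separated by
#' `-`, with optional bracketed groups for additional guanines (base pairs
#' or triads) stacked on external tetrads, e.g. `"sa[a]-sa[a-a]sa-sa[a]"`.
#' The compact repeat form `"(sa)4"` expands to four identical tracts.
#'
#' @param s A GBA string.
#' @return An object of class `gba`: a list of elements, each a tract
#'   (letters) or a bracket group, preserving separators so the canonical
#'   string round-trips through [format_gba()].
#' @export
parse_gba <- function(s) {
  stopifnot(is.character(s), length(s) == 1, !is.na(s))
  raw <- gsub("[[:space:]]", "", s)
  # compact repeat form: "(sa)4"
  m <- regmatches(raw, regexec("^\\(([sa]+)\\)([0-9]+)$", raw))[[1]]
  if (length(m) == 3) {
    unit <- strsplit(m[2], "")[[1]]
    n <- as.integer(m[3])
    elements <- lapply(seq_len(n), function(i) {
      list(type = "tract", letters = unit, sep = if (i == 1) "" else "-")
    })
    return(structure(list(elements = elements, compact = TRUE), class = "gba"))
  }
  chars <- strsplit(raw, "")[[1]]
  if (length(chars) == 0) stop("empty GBA string", call. = FALSE)
  elements <- list()
  i <- 1L
  pending_sep <- ""
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "-") {
      if (pending_sep == "-" || length(elements) == 0) {
        stop("malformed GBA string: stray '-'", call. = FALSE)
      }
      pending_sep <- "-"
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      inner <- character(0)
      while (j <= length(chars) && chars[j] != "]") {
        inner <- c(inner, chars[j]); j <- j + 1L
      }
      if (j > length(chars)) stop("unbalanced '[' in GBA string", call. = FALSE)
      bad <- setdiff(inner, c("s", "a", "-"))
      if (length(bad) > 0 || length(inner) == 0) {
        stop("illegal character in GBA bracket group: ",
             paste(bad, collapse = ""), call. = FALSE)
      }
      elements[[length(elements) + 1L]] <- list(
        type = "bracket", raw = paste(inner, collapse = ""),
        letters = inner[inner != "-"], sep = pending_sep
      )
      pending_sep <- ""
      i <- j + 1L
    } else if (ch %in% c("s", "a")) {
      j <- i
      run <- character(0)
      while (j <= length(chars) && chars[j] %in% c("s", "a")) {
        run <- c(run, chars[j]); j <- j + 1L
      }
      elements[[length(elements) + 1L]] <- list(
        type = "tract", letters = run, sep = pending_sep
      )
      pending_sep <- ""
      i <- j
    } else {
      stop("illegal character '", ch, "' in GBA string (expected s, a, -, [, ])",
           call. = FALSE)
    }
  }
  if (pending_sep == "-") stop("malformed GBA string: trailing '-'", call. = FALSE)
  structure(list(elements = elements, compact = FALSE), class = "gba")
}

#' Format a parsed GBA back to its canonical string
#'
#' Four identical bracket-free tracts collapse to the compact `"(sa)4"`
#' form; otherwise elements are joined with their original separators.
#'
#' @param x A `gba` object.
#' @return The canonical GBA string.
#' @export
format_gba <- function(x) {
  stopifnot(inherits(x, "gba"))
  el <- x$elements
  tracts <- Filter(function(e) e$type == "tract", el)
  if (length(tracts) == length(el) && length(tracts) >= 2) {
    strs <- vapply(tracts, function(e) paste(e$letters, collapse = ""), "")
    if (length(unique(strs)) == 1) {
      return(sprintf("(%s)%d", strs[1], length(strs)))
    }
  }
  paste0(vapply(el, function(e) {
    body <- if (e$type == "tract") paste(e$letters, collapse = "")
            else paste0("[", e$raw, "]")
    paste0(e$sep, body)
  }, ""), collapse = "")
}

#' @export
print.gba <- function(x, ...) {
  cat("<gba> ", format_gba(x), "\n", sep = "")
  invisible(x)
}

stack_core_classes <- c("aa", "as", "sa", "ss")
stack_interface_classes <- c("aa^5/6r", "aa^6r", "aa^5r", "aa^p6r")

#' Stack-count container
#'
#' Counts of guanine stacking steps by class: core classes `aa`, `as`,
#' `sa`, `ss`; dimer/unit interface classes `aa^5/6r`, `aa^6r`, `aa^5r`,
#' `aa^p6r`; and a separately-kept bracketed (capping/triad) partition.
#'
#' @param core,interface,bracketed Named non-negative integer vectors
#'   (subsets of the class sets above).
#' @return An object of class `stack_count`.
#' @export
stack_count <- function(core = integer(0), interface = integer(0),
                        bracketed = integer(0)) {
  fill <- function(x, classes) {
    bad <- setdiff(names(x), classes)
    if (length(bad) > 0) stop("unknown stack class: ",
                              paste(bad, collapse = ", "), call. = FALSE)
    out <- stats::setNames(integer(length(classes)), classes)
    out[names(x)] <- as.integer(x)
    if (any(out < 0)) stop("stack counts must be >= 0", call. = FALSE)
    out
  }
  structure(
    list(core = fill(core, stack_core_classes),
         interface = fill(interface, stack_interface_classes),
         bracketed = fill(bracketed, c(stack_core_classes,
                                       stack_interface_classes))),
    class = "stack_count"
  )
}

#' @export
print.stack_count <- function(x, ...) {
  cat("<stack_count> ", format_stack_string(x), "\n", sep = "")
  invisible(x)
}

#' Derive stack counts from a parsed GBA descriptor
#'
#' Within each tract, every adjacent letter pair contributes one stack, the
#' first letter being the 5' partner (`sa` = 5'-syn/anti-3'). A bracketed
#' single capping letter adjacent to exactly one tract pairs with that
#' tract's facing core letter and is counted in the bracketed partition.
#' Bracket groups that are multi-letter, dashed, or flanked by tracts on
#' both sides are ambiguous: the function refuses and the explicit printed
#' stack string must be supplied instead.
#'
#' For structures built from stacked sub-units (left-handed Z-G4s),
#' `interface_after` names the tetrad index (stack step within each tract)
#' at which the unit-to-unit interface occurs; those steps are counted as
#' interface stacks with the overlap annotation `interface_overlap`.
#'
#' @param x A `gba` object or GBA string.
#' @param interface_after Integer vector of within-tract step indices that
#'   are unit interfaces (e.g. `2` for a 4-tetrad core of two 2-tetrad
#'   units), or `NULL`.
#' @param interface_overlap Overlap annotation for interface steps:
#'   `"5/6r"`, `"6r"`, `"5r"` or `"p6r"`.
#' @return A `stack_count`.
#' @examples
#' format_stack_string(stacks_from_gba("(aaa)4"))        # "8aa"
#' format_stack_string(stacks_from_gba("asa-sas-asa-sas")) # "4as·4sa"
#' @export
stacks_from_gba <- function(x, interface_after = NULL,
                            interface_overlap = c("5/6r", "6r", "5r", "p6r")) {
  interface_overlap <- match.arg(interface_overlap)
  if (is.character(x)) x <- parse_gba(x)
  stopifnot(inherits(x, "gba"))
  el <- x$elements
  core <- integer(0)
  interface <- integer(0)
  bracketed <- integer(0)
  bump <- function(tab, cls) {
    tab[cls] <- (if (cls %in% names(tab)) tab[[cls]] else 0L) + 1L
    tab
  }
  for (k in seq_along(el)) {
    e <- el[[k]]
    if (e$type == "tract") {
      n <- length(e$letters)
      if (n >= 2) {
        for (p in seq_len(n - 1)) {
          cls <- paste0(e$letters[p], e$letters[p + 1])
          if (!is.null(interface_after) && p %in% interface_after) {
            icls <- paste0(cls, "^", interface_overlap)
            if (!icls %in% stack_interface_classes) {
              stop("interface step '", cls, "' has no '", interface_overlap,
                   "' overlap class", call. = FALSE)
            }
            interface <- bump(interface, icls)
          } else {
            core <- bump(core, cls)
          }
        }
      }
    } else { # bracket
      if (grepl("-", e$raw) || length(e$letters) != 1) {
        stop("ambiguous bracket group '[", e$raw, "]': supply the explicit ",
             "stack string instead (see parse_stack_string)", call. = FALSE)
      }
      prev_adj <- k > 1 && el[[k - 1]]$type == "tract" && e$sep == ""
      next_adj <- k < length(el) && el[[k + 1]]$type == "tract" &&
        el[[k + 1]]$sep == ""
      if (prev_adj && next_adj) {
        stop("ambiguous bracket group '[", e$raw, "]' between two adjacent ",
             "tracts: supply the explicit stack string instead", call. = FALSE)
      }
      if (prev_adj) {
        # cap on the 3' side of the preceding tract
        core_letter <- utils::tail(el[[k - 1]]$letters, 1)
        bracketed <- bump(bracketed, paste0(core_letter, e$letters))
      } else if (next_adj) {
        # cap on the 5' side of the following tract
        core_letter <- el[[k + 1]]$letters[1]
        bracketed <- bump(bracketed, paste0(e$letters, core_letter))
      } else {
        stop("bracket group '[", e$raw, "]' is not adjacent to any tract",
             call. = FALSE)
      }
    }
  }
  stack_count(core = core, interface = interface, bracketed = bracketed)
}

#' Parse and format stack-count strings
#'
#' Stack strings list counts per class joined by a middle dot, e.g.
#' `"3aa·4sa·1ss"` or `"8aa·4aa^5/6r"`; an optional leading bracketed group
#' (`"[3aa·1as]·4sa"`) holds capping/triad stacks. `.` and `*` are accepted
#' as ASCII separator substitutes on input; the canonical output uses the
#' middle dot and orders classes aa, as, sa, ss, then interface classes.
#'
#' @param s A stack string.
#' @return A `stack_count`.
#' @export
parse_stack_string <- function(s) {
  stopifnot(is.character(s), length(s) == 1, !is.na(s))
  raw <- gsub("[[:space:]]", "", s)
  bracketed_part <- NULL
  m <- regmatches(raw, regexec("^\\[([^]]+)\\]", raw))[[1]]
  if (length(m) == 2) {
    bracketed_part <- m[2]
    raw <- sub("^\\[[^]]+\\]", "", raw)
    raw <- sub("^[·.*]", "", raw)
  }
  parse_tokens <- function(txt) {
    if (!nzchar(txt)) return(integer(0))
    toks <- strsplit(txt, "[·.*]", perl = TRUE)[[1]]
    out <- integer(0)
    for (tk in toks) {
      tm <- regmatches(tk,
        regexec("^([0-9]+)(aa|as|sa|ss)(\\^(5/6r|6r|5r|p6r))?$", tk))[[1]]
      if (length(tm) == 0) {
        stop("unrecognized stack token '", tk, "'", call. = FALSE)
      }
      cls <- paste0(tm[3], if (nzchar(tm[4])) tm[4] else "")
      out[cls] <- (if (cls %in% names(out)) out[[cls]] else 0L) + as.integer(tm[2])
    }
    out
  }
  main <- parse_tokens(raw)
  is_iface <- names(main) %in% stack_interface_classes
  stack_count(core = main[!is_iface], interface = main[is_iface],
              bracketed = parse_tokens(bracketed_part %||% ""))
}

#' @rdname parse_stack_string
#' @param x A `stack_count`.
#' @return `format_stack_string()`: the canonical stack string.
#' @export
format_stack_string <- function(x) {
  stopifnot(inherits(x, "stack_count"))
  fmt <- function(tab) {
    tab <- tab[tab > 0]
    if (length(tab) == 0) return(NULL)
    paste(sprintf("%d%s", unname(tab), names(tab)), collapse = "·")
  }
  parts <- c(
    if (!is.null(b <- fmt(x$bracketed))) paste0("[", b, "]"),
    fmt(x$core),
    fmt(x$interface)
  )
  if (length(parts) == 0) return("0")
  paste(parts, collapse = "·")
}

#' Total number of stacks in a `stack_count`
#'
#' @param x A `stack_count`.
#' @param include_bracketed Include the bracketed partition (default FALSE).
#' @return Integer total.
#' @export
total_stacks <- function(x, include_bracketed = FALSE) {
  stopifnot(inherits(x, "stack_count"))
  sum(x$core) + sum(x$interface) +
    if (include_bracketed) sum(x$bracketed) else 0L
}

#' Load the bundled 30-structure reference panel
#'
#' A curated panel of G4-forming oligonucleotides of known structure,
#' annotated with salt condition, topology, conformer, groove widths,
#' tetrad/loop progression, groove-type combination group, tetrad
#' handedness, the GBA string and the GBA-stack composition. On load,
#' every bracket-free entry's GBA string is checked for consistency against
#' its printed stack string (Z-parallel entries are checked with the
#' two-unit interface at tetrad step 2).
#'
#' @param check Run the integrity/consistency checks (default TRUE).
#' @return A tibble with 30 rows.
#' @export
load_reference_panel <- function(check = TRUE) {
  path <- system.file("extdata", "reference_panel.tsv", package = "quadsig",
                      mustWork = TRUE)
  panel <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                             stringsAsFactors = FALSE, check.names = FALSE,
                             encoding = "UTF-8", comment.char = "")
  panel <- tibble::as_tibble(panel)
  if (!check) return(panel)
  if (nrow(panel) != 30) stop("reference panel corrupted: expected 30 entries",
                              call. = FALSE)
  for (i in seq_len(nrow(panel))) {
    row <- panel[i, ]
    nt_seq(row$sequence)
    if (nchar(row$grooves) != 4 ||
        grepl("[^wnm]", row$grooves)) {
      stop("reference panel corrupted: bad grooves for ", row$name,
           call. = FALSE)
    }
    parsed <- parse_gba(row$gba)
    printed <- parse_stack_string(row$gba_stacks)
    has_brackets <- any(vapply(parsed$elements,
                               function(e) e$type == "bracket", logical(1)))
    if (!has_brackets) {
      derived <- if (identical(row$topology, "z-parallel")) {
        stacks_from_gba(parsed, interface_after = 2)
      } else {
        stacks_from_gba(parsed)
      }
      if (!identical(format_stack_string(derived),
                     format_stack_string(printed))) {
        stop("reference panel corrupted: GBA/stack mismatch for ", row$name,
             call. = FALSE)
      }
    }
  }
  panel
}
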