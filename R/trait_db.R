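#' Construct a GIFT (pathway) definition
#'
#' A GIFT element is a curated metabolic pathway or module, decomposed into an
#' ordered list of steps. Each step is satisfied by any one of its alternative
#' clauses; a clause is a set of function identifiers (KEGG orthologs, EC
#' numbers, ...) that are jointly required for full credit.
#'
#' Codes are hierarchical by prefix: the first character is the domain
#' (`"B"` biosynthesis, `"D"` degradation), the first three characters the
#' function (e.g. `"B02"` amino-acid derivatives), the full code the element
#' (e.g. `"B0211"` lysine).
#'
#' @param code element code, e.g. `"B0211"`.
#' @param name human-readable pathway name.
#' @param steps list of steps; each step is a list of clauses; each clause a
#'   character vector of identifiers.
#' @return an object of class `gift_definition`.
#' @examples
#' gift_definition("B0211", "lysine biosynthesis",
#'                 list(list(c("K00928", "K00133")), list("K01714", "K00215")))
#' @export
gift_definition <- function(code, name, steps) {
  stopifnot(is.character(code), length(code) == 1L, nzchar(code))
  if (grepl("\\s", code)) stop("GIFT code must not contain whitespace: ", code)
  if (length(steps) < 1L) stop("GIFT ", code, " must have at least one step")
  steps <- lapply(steps, function(st) {
    if (!is.list(st)) st <- list(st)
    if (length(st) < 1L) stop("GIFT ", code, ": step with no clauses")
    lapply(st, function(cl) {
      cl <- as.character(cl)
      if (length(cl) < 1L || any(!nzchar(cl)) || any(grepl("\\s", cl)))
        stop("GIFT ", code, ": malformed clause identifiers")
      unique(cl)
    })
  })
  structure(
    list(code = code,
         domain_code = substr(code, 1L, 1L),
         function_code = substr(code, 1L, 3L),
         name = as.character(name),
         steps = steps),
    class = "gift_definition")
}

#' Construct a trait database
#'
#' The trait database drives distillation: a catalogue of
#' [gift_definition()] elements plus an optional mapping from element codes to
#' functional-category labels (used by [aggregate_categories()]). When a code
#' has no explicit category, its three-character function prefix is used.
#'
#' @param elements list of [gift_definition()] objects.
#' @param category_map named character vector, names are GIFT codes, values
#'   category labels. May be `NULL`.
#' @return an object of class `trait_db`.
#' @seealso [parse_trait_db()], [validate_trait_db()]
#' @export
trait_db <- function(elements, category_map = NULL) {
  codes <- vapply(elements, `[[`, character(1), "code")
  if (anyDuplicated(codes))
    stop("duplicate GIFT codes: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "))
  elements <- elements[order(codes)]
  names(elements) <- sort(codes)
  if (!is.null(category_map)) {
    category_map <- category_map[order(names(category_map))]
    storage.mode(category_map) <- "character"
  }
  structure(list(elements = elements, category_map = category_map),
            class = "trait_db")
}

#' @export
print.trait_db <- function(x, ...) {
  cat("Trait database:", length(x$elements), "GIFT elements,",
      length(unique(gift_categories(x))), "functional categories\n")
  fn <- table(vapply(x$elements, `[[`, character(1), "domain_code"))
  cat("Domains:", paste(names(fn), fn, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' GIFT codes of a trait database
#' @param db a `trait_db`.
#' @return character vector of element codes, sorted.
#' @export
gift_codes <- function(db) {
  stopifnot(inherits(db, "trait_db"))
  names(db$elements)
}

#' Category label of every GIFT element
#'
#' Falls back to the three-character function prefix for codes absent from the
#' database's category map.
#'
#' @param db a `trait_db`.
#' @return named character vector: code -> category.
#' @export
gift_categories <- function(db) {
  stopifnot(inherits(db, "trait_db"))
  codes <- gift_codes(db)
  cats <- substr(codes, 1L, 3L)
  names(cats) <- codes
  if (!is.null(db$category_map)) {
    hit <- intersect(names(db$category_map), codes)
    cats[hit] <- db$category_map[hit]
  }
  cats
}

# Parse one serialized clause string, e.g. "K00928&K00133|K01714".
# "|" separates alternative clauses, "&" joins jointly-required identifiers.
parse_clause_string <- function(s, where = "") {
  if (length(s) != 1L || is.na(s) || !nzchar(trimws(s)))
    stop("empty clause field", where)
  s <- trimws(s)
  clauses <- strsplit(s, "|", fixed = TRUE)[[1]]
  clauses <- lapply(clauses, function(cl) {
    ids <- trimws(strsplit(cl, "&", fixed = TRUE)[[1]])
    if (length(ids) == 0L || any(!nzchar(ids)))
      stop("malformed clause string '", s, "'", where)
    unique(ids)
  })
  clauses
}

deparse_clauses <- function(clauses) {
  paste(vapply(clauses, paste, character(1), collapse = "&"), collapse = "|")
}

#' Parse a trait-definition table
#'
#' Reads a delimited table with columns `code,name,step,clause` (one row per
#' pathway step; the clause column serializes alternative clauses with `"|"`
#' and jointly-required identifiers with `"&"`), plus an optional category map
#' with columns `code,category`.
#'
#' Duplicate identical `(code, step, clause)` rows are collapsed; the same
#' `(code, step)` appearing with different clause strings is a validation
#' error. Parsing is row-order independent: elements are ordered by code and
#' steps by their step index.
#'
#' @param path path to the definition table (CSV or TSV by extension).
#' @param category_path optional path to the `code,category` map.
#' @return a validated [trait_db()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("code,name,step,clause",
#'              "B0211,lysine biosynthesis,1,K00928&K00133",
#'              "B0211,lysine biosynthesis,2,K01714|K00215"), f)
#' db <- parse_trait_db(f)
#' @export
parse_trait_db <- function(path, category_path = NULL) {
  tab <- read_delim_auto(path)
  need <- c("code", "name", "step", "clause")
  if (!all(need %in% names(tab)))
    stop("trait-definition table must have columns ",
         paste(need, collapse = ", "))
  tab$code <- trimws(as.character(tab$code))
  tab$step <- as.integer(tab$step)
  if (anyNA(tab$step)) stop("non-integer step index in trait-definition table")
  key <- paste(tab$code, tab$step, tab$clause, sep = "\r")
  tab <- tab[!duplicated(key), , drop = FALSE]
  conflict <- unique(tab$code[duplicated(paste(tab$code, tab$step, sep = "\r"))])
  if (length(conflict))
    stop("conflicting step definitions for code(s): ",
         paste(conflict, collapse = ", "))
  elements <- lapply(split(tab, tab$code), function(rows) {
    rows <- rows[order(rows$step), , drop = FALSE]
    steps <- lapply(seq_len(nrow(rows)), function(i)
      parse_clause_string(rows$clause[i],
                          where = sprintf(" (code %s, step %d)",
                                          rows$code[i], rows$step[i])))
    gift_definition(rows$code[1], rows$name[1], steps)
  })
  category_map <- NULL
  if (!is.null(category_path)) {
    cm <- read_delim_auto(category_path)
    if (!all(c("code", "category") %in% names(cm)))
      stop("category map must have columns code, category")
    category_map <- stats::setNames(as.character(cm$category),
                                    trimws(as.character(cm$code)))
  }
  db <- trait_db(elements, category_map)
  findings <- validate_trait_db(db)
  if (length(findings))
    stop("invalid trait database: ", paste(findings, collapse = "; "))
  db
}

#' Serialize a trait database to its canonical table
#'
#' Writes one row per `(code, step)` in canonical order (code, then step
#' index); [parse_trait_db()] of the written file reproduces the database.
#'
#' @param db a `trait_db`.
#' @param path output file; dialect (CSV/TSV) chosen by extension.
#' @param category_path optional output for the category map.
#' @return `path`, invisibly.
#' @export
write_trait_db <- function(db, path, category_path = NULL) {
  stopifnot(inherits(db, "trait_db"))
  rows <- do.call(rbind, lapply(db$elements, function(el) {
    data.frame(code = el$code, name = el$name,
               step = seq_along(el$steps),
               clause = vapply(el$steps, deparse_clauses, character(1)),
               stringsAsFactors = FALSE)
  }))
  write_delim_auto(rows, path)
  if (!is.null(category_path) && !is.null(db$category_map)) {
    cm <- data.frame(code = names(db$category_map),
                     category = unname(db$category_map),
                     stringsAsFactors = FALSE)
    write_delim_auto(cm, category_path)
  }
  invisible(path)
}

#' Validate a trait database
#'
#' Checks the structural invariants and returns findings rather than raising:
#' duplicate element codes, elements without steps or with empty clauses, and
#' category-map keys that name no element.
#'
#' @param db a `trait_db` (or a bare list shaped like one).
#' @return character vector of findings; empty when all invariants hold.
#' @export
validate_trait_db <- function(db) {
  findings <- character(0)
  codes <- vapply(db$elements, `[[`, character(1), "code")
  dup <- unique(codes[duplicated(codes)])
  if (length(dup))
    findings <- c(findings, paste0("duplicate code ", dup))
  for (el in db$elements) {
    if (length(el$steps) == 0L)
      findings <- c(findings, paste0("element ", el$code, " has no steps"))
    nid <- vapply(el$steps, function(st)
      min(lengths(st), length(st)), numeric(1))
    if (any(nid == 0))
      findings <- c(findings, paste0("element ", el$code, " has an empty clause"))
    if (!startsWith(el$code, el$function_code))
      findings <- c(findings, paste0("element ", el$code,
                                     " inconsistent function code"))
  }
  orphan <- setdiff(names(db$category_map), codes)
  if (length(orphan))
    findings <- c(findings,
                  paste0("category map key ", orphan, " matches no element"))
  findings
}

#' GIFT codes belonging to a functional category
#'
#' @param db a `trait_db`.
#' @param category category label (case-sensitive).
#' @return character vector of member codes, ordered by code.
#' @export
elements_of_category <- function(db, category) {
  cats <- gift_categories(db)
  if (!category %in% cats)
    stop("unknown functional category: '", category, "'")
  sort(names(cats)[cats == category])
}

#' Bundled study-scale trait database (synthetic stand-in)
#'
#' Returns the study-scale trait database shipped with the package: 170 GIFT
#' elements with hierarchical biosynthesis/degradation codes and a functional
#' category map. The content is a synthetic stand-in constructed to the
#' cardinality and code structure of the curated distillR-style catalogue
#' (including the elements B0101-B0103, B0211, B0401-B0403, B0701, B0805 and
#' D0509 referenced throughout the analyses); it is not the curated catalogue
#' itself and carries no biological meaning beyond its structure.
#'
#' @return a [trait_db()] with 170 elements.
#' @export
study_trait_db <- function() {
  parse_trait_db(
    system.file("extdata", "gift_db_170_synthetic.csv", package = "magifts",
                mustWork = TRUE),
    system.file("extdata", "gift_categories_170_synthetic.csv",
                package = "magifts", mustWork = TRUE))
}
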