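#' Base-editor conversion chemistry
#'
#' A \code{BaseConversion} describes which base an editor converts and into
#' what. Glycosylase-based editors excise their source base, leaving an abasic
#' site whose repair yields a spectrum of products: for a gTBE the T is
#' predominantly replaced by C or G (T-to-S) with a minor T-to-A fraction; for
#' gCBE/CGBE-class editors C-to-G dominates with secondary C-to-T.
#'
#' @slot source_base single character, the edited base.
#' @slot product_bases ordered character vector of product bases.
#' @slot predominant subset of \code{product_bases} flagged as major products.
#' @exportClass BaseConversion
setClass("BaseConversion",
  representation(source_base = "character",
                 product_bases = "character",
                 predominant = "character"))

setValidity("BaseConversion", function(object) {
  msg <- character()
  if (length(object@source_base) != 1L || !object@source_base %in% BASES)
    msg <- c(msg, "source_base must be one of A, C, G, T")
  if (length(object@product_bases) == 0L)
    msg <- c(msg, "product_bases must be non-empty")
  if (!all(object@product_bases %in% BASES))
    msg <- c(msg, "product_bases must be nucleotides")
  if (object@source_base %in% object@product_bases)
    msg <- c(msg, "source_base must not be among product_bases")
  if (anyDuplicated(object@product_bases))
    msg <- c(msg, "product_bases must be unique")
  if (!all(object@predominant %in% object@product_bases))
    msg <- c(msg, "predominant must be a subset of product_bases")
  if (length(msg)) msg else TRUE
})

#' @param source_base,product_bases,predominant see slots.
#' @rdname BaseConversion-class
#' @export
BaseConversion <- function(source_base, product_bases,
                           predominant = product_bases) {
  new("BaseConversion", source_base = source_base,
      product_bases = product_bases, predominant = predominant)
}

#' Protospacer editing window
#'
#' Editing windows are 1-based protospacer positions with the PAM at
#' positions 21--23. The editable range is any position with detectable
#' activity; the optimal window is the high-efficiency subrange; \code{peak}
#' (optional, \code{NA} when unknown) is the single most efficient position.
#'
#' @slot editable_start,editable_end,optimal_start,optimal_end integer bounds.
#' @slot peak integer or NA.
#' @exportClass EditingWindow
setClass("EditingWindow",
  representation(editable_start = "integer", editable_end = "integer",
                 optimal_start = "integer", optimal_end = "integer",
                 peak = "integer"))

setValidity("EditingWindow", function(object) {
  b <- c(object@editable_start, object@optimal_start,
         object@optimal_end, object@editable_end)
  if (any(is.na(b))) return("window bounds must not be NA")
  if (!(1L <= object@editable_start &&
        object@editable_start <= object@optimal_start &&
        object@optimal_start <= object@optimal_end &&
        object@optimal_end <= object@editable_end &&
        object@editable_end <= 20L))
    return("need 1 <= editable_start <= optimal_start <= optimal_end <= editable_end <= 20")
  if (!is.na(object@peak) &&
      (object@peak < object@optimal_start || object@peak > object@optimal_end))
    return("peak must lie inside the optimal window")
  TRUE
})

#' @param editable,optimal length-2 integer vectors (start, end). An editor
#'   whose only published window is a single range passes it as both.
#' @param peak optional peak position.
#' @rdname EditingWindow-class
#' @export
EditingWindow <- function(editable, optimal = editable, peak = NA) {
  new("EditingWindow",
      editable_start = as.integer(editable[1]), editable_end = as.integer(editable[2]),
      optimal_start = as.integer(optimal[1]), optimal_end = as.integer(optimal[2]),
      peak = as.integer(peak))
}

#' A base-editor specification
#'
#' Bundles a name, conversion chemistry, editing window, PAM and nickase
#' label. The PAM is a 3-letter IUPAC pattern applied at protospacer
#' positions 21--23 on the protospacer strand (NGG for SpCas9, NGN for SpG).
#'
#' @slot name editor name.
#' @slot conversion a \linkS4class{BaseConversion}.
#' @slot window an \linkS4class{EditingWindow}.
#' @slot pam 3-letter IUPAC string.
#' @slot nickase free-text label (metadata only).
#' @exportClass EditorSpec
setClass("EditorSpec",
  representation(name = "character", conversion = "BaseConversion",
                 window = "EditingWindow", pam = "character",
                 nickase = "character"))

setValidity("EditorSpec", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("name must be a non-empty string")
  if (length(object@pam) != 1L || nchar(object@pam) != 3L)
    return("pam must be a 3-character IUPAC pattern")
  ok <- tryCatch({ .check_iupac(object@pam); TRUE }, error = function(e) FALSE)
  if (!ok) return("pam contains invalid IUPAC codes")
  TRUE
})

#' @param name,conversion,window,pam,nickase see slots.
#' @rdname EditorSpec-class
#' @export
EditorSpec <- function(name, conversion, window, pam = "NGG",
                       nickase = "nCas9-D10A") {
  new("EditorSpec", name = name, conversion = conversion, window = window,
      pam = pam, nickase = nickase)
}

#' Registry of base editors
#'
#' An immutable name-to-\linkS4class{EditorSpec} map. Subset with \code{[[}
#' by editor name.
#'
#' @slot editors named list of EditorSpec.
#' @exportClass EditorRegistry
setClass("EditorRegistry", representation(editors = "list"))

setValidity("EditorRegistry", function(object) {
  if (!all(vapply(object@editors, is, logical(1), "EditorSpec")))
    return("all elements must be EditorSpec")
  nm <- names(object@editors)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    return("editor names must be unique and non-empty")
  if (!identical(nm, unname(vapply(object@editors, function(e) e@name,
                                   character(1)))))
    return("list names must equal the editors' name slots")
  TRUE
})

#' @param editors list of EditorSpec objects.
#' @rdname EditorRegistry-class
#' @export
EditorRegistry <- function(editors) {
  names(editors) <- vapply(editors, function(e) e@name, character(1))
  new("EditorRegistry", editors = editors)
}

#' @export
setMethod("names", "EditorRegistry", function(x) names(x@editors))

#' @export
setMethod("length", "EditorRegistry", function(x) length(x@editors))

#' @export
setMethod("[[", "EditorRegistry", function(x, i) {
  e <- x@editors[[i]]
  if (is.null(e)) stop("unknown editor: ", i)
  e
})

setMethod("show", "EditorSpec", function(object) {
  conv <- object@conversion
  w <- object@window
  cat(sprintf("EditorSpec %s: %s->{%s} (predominant %s), PAM %s,\n",
              object@name, conv@source_base,
              paste(conv@product_bases, collapse = ","),
              paste(conv@predominant, collapse = ","), object@pam))
  cat(sprintf("  editable window %d-%d, optimal %d-%d%s\n",
              w@editable_start, w@editable_end, w@optimal_start, w@optimal_end,
              if (is.na(w@peak)) "" else sprintf(", peak %d", w@peak)))
})

setMethod("show", "EditorRegistry", function(object) {
  cat("EditorRegistry with", length(object), "editors:\n ",
      paste(names(object), collapse = ", "), "\n")
})

## chemistries shared across editor families
.tbe_conversion <- function() BaseConversion("T", c("C", "G", "A"), c("C", "G"))
.gcbe_conversion <- function() BaseConversion("C", c("G", "T", "A"), "G")
.cbe_conversion <- function() BaseConversion("C", "T", "T")
.abe_conversion <- function() BaseConversion("A", "G", "G")
.ggbe_conversion <- function() BaseConversion("G", c("C", "T"), c("C", "T"))

#' Built-in editor registry
#'
#' Returns the registry of editors characterized alongside the gTBE/gCBE
#' family, with their published editable/optimal windows, plus canonical
#' ABE/CBE (community-convention window optimal 4--8, editable 3--9, not
#' restated by the characterization itself) and gGBE (window unpublished,
#' same conventional default). Editors for which only a single window range
#' is published carry it as both editable and optimal.
#'
#' @return an \linkS4class{EditorRegistry}.
#' @examples
#' reg <- builtinEditors()
#' reg[["gTBEv3"]]
#' @export
builtinEditors <- function() {
  tbe <- .tbe_conversion(); gcbe <- .gcbe_conversion()
  EditorRegistry(list(
    EditorSpec("gTBEv3", tbe, EditingWindow(c(2, 11), c(3, 7), peak = 5)),
    EditorSpec("gTBEv4", tbe, EditingWindow(c(7, 13))),
    EditorSpec("gTBEv5", tbe, EditingWindow(c(5, 9))),
    EditorSpec("TSBE3", tbe, EditingWindow(c(4, 9))),
    EditorSpec("DAF-TBE", tbe, EditingWindow(c(2, 6))),
    EditorSpec("DAF-TBE2", tbe, EditingWindow(c(9, 13))),
    EditorSpec("gCBEv2", gcbe, EditingWindow(c(2, 9), c(2, 6))),
    EditorSpec("gCBEv3", gcbe, EditingWindow(c(2, 11))),
    EditorSpec("CGBE1", gcbe, EditingWindow(c(4, 10), c(5, 7))),
    EditorSpec("CGBE-CDG", gcbe, EditingWindow(c(2, 9))),
    EditorSpec("DAF-CBE", gcbe, EditingWindow(c(2, 9))),
    EditorSpec("DAF-CBE2", gcbe, EditingWindow(c(9, 12))),
    EditorSpec("ABE", .abe_conversion(), EditingWindow(c(3, 9), c(4, 8))),
    EditorSpec("CBE", .cbe_conversion(), EditingWindow(c(3, 9), c(4, 8))),
    EditorSpec("gGBE", .ggbe_conversion(), EditingWindow(c(3, 9), c(4, 8)))
  ))
}

#' Can an editor edit a given base at a given protospacer position?
#'
#' @param editor an \linkS4class{EditorSpec}.
#' @param base nucleotide as read on the protospacer strand.
#' @param position 1-based protospacer position (1..20, PAM at 21--23).
#' @param mode \code{"optimal"} (default) or \code{"editable"}.
#' @return \code{TRUE} iff \code{base} is the editor's source base and
#'   \code{position} lies in the requested window.
#' @examples
#' canEdit(builtinEditors()[["gTBEv3"]], "T", 5)
#' @export
canEdit <- function(editor, base, position,
                    mode = c("optimal", "editable")) {
  stopifnot(is(editor, "EditorSpec"))
  mode <- match.arg(mode)
  position <- as.integer(position)
  if (any(position < 1L | position > 20L))
    stop("position must be in 1..20")
  w <- editor@window
  lo <- if (mode == "optimal") w@optimal_start else w@editable_start
  hi <- if (mode == "optimal") w@optimal_end else w@editable_end
  base == editor@conversion@source_base & position >= lo & position <= hi
}

## products used for design-time intended edits: predominant only
intendedProducts <- function(editor) editor@conversion@predominant

.editor_to_list <- function(e) {
  w <- e@window
  list(name = e@name,
       conversion = list(source = e@conversion@source_base,
                         products = as.list(e@conversion@product_bases),
                         predominant = as.list(e@conversion@predominant)),
       window = list(editable = c(w@editable_start, w@editable_end),
                     optimal = c(w@optimal_start, w@optimal_end),
                     peak = if (is.na(w@peak)) NULL else w@peak),
       pam = e@pam, nickase = e@nickase)
}

.editor_from_list <- function(x) {
  peak <- x$window$peak
  if (is.null(peak) || length(peak) == 0L) peak <- NA
  EditorSpec(x$name,
             BaseConversion(x$conversion$source,
                            unlist(x$conversion$products),
                            unlist(x$conversion$predominant)),
             EditingWindow(unlist(x$window$editable), unlist(x$window$optimal),
                           peak = peak),
             pam = x$pam, nickase = x$nickase)
}

#' Read / write editor configuration (JSON)
#'
#' The JSON config lists editors with name, conversion, window, pam and
#' nickase fields. \code{writeEditorConfig(builtinEditors(), path)} followed
#' by \code{readEditorConfig(path)} round-trips the registry exactly; the
#' shipped default config (\code{system.file("extdata", "editors.json",
#' package = "gbekit")}) reproduces \code{builtinEditors()}.
#'
#' @param path file path.
#' @param registry an \linkS4class{EditorRegistry}.
#' @return \code{readEditorConfig} returns an EditorRegistry;
#'   \code{writeEditorConfig} returns \code{path} invisibly.
#' @export
readEditorConfig <- function(path) {
  x <- jsonlite::read_json(path)
  EditorRegistry(lapply(x$editors, .editor_from_list))
}

#' @rdname readEditorConfig
#' @export
writeEditorConfig <- function(registry, path) {
  stopifnot(is(registry, "EditorRegistry"))
  x <- list(editors = lapply(registry@editors, .editor_to_list))
  names(x$editors) <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
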