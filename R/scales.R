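#' Define a symptom rating scale
#'
#' A symptom scale is the ordered set of ordinal items over which all
#' symptom-level analyses index: each item has an identifier, a label and a
#' maximum severity level (items are scored on consecutive integers
#' \code{0..max_level}).
#'
#' @param scale_id One of \code{"HAMD17"}, \code{"BDI_I"}, \code{"BDI_II"},
#'   or \code{"CUSTOM"} for an ad-hoc instrument (simulation designs,
#'   non-standard scale variants).
#' @param items Data frame with columns \code{item_id}, \code{label},
#'   \code{max_level}.
#'
#' @return An object of class \code{symptom_scale}: a list with elements
#'   \code{scale_id} and \code{items}.
#'
#' @details The HAM-D-17 must have 17 items and either BDI version 21 items;
#'   a \code{CUSTOM} scale may have any number. Item ids must be unique and
#'   every \code{max_level} at least 1. Item maxima are data, not code:
#'   trials differ in the scale variant scored, so level structures are
#'   configurable per item.
#'
#' @seealso [hamd17_scale()], [bdi_scale()], [read_scale_yaml()]
#' @export
symptom_scale <- function(scale_id, items) {
  scale_id <- match.arg(scale_id, c("HAMD17", "BDI_I", "BDI_II", "CUSTOM"))
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  req <- c("item_id", "label", "max_level")
  if (!all(req %in% names(items)))
    validation_error("scale items need columns item_id, label, max_level")
  items <- items[, req]
  items$item_id <- as.character(items$item_id)
  items$label <- as.character(items$label)
  items$max_level <- as.integer(items$max_level)
  if (scale_id != "CUSTOM") {
    n_expected <- if (scale_id == "HAMD17") 17L else 21L
    if (nrow(items) != n_expected)
      validation_error(sprintf("%s requires %d items, got %d",
                               scale_id, n_expected, nrow(items)))
  }
  if (nrow(items) < 1L) validation_error("scale needs at least one item")
  if (anyDuplicated(items$item_id))
    validation_error("duplicate item_id in scale")
  if (any(items$max_level < 1L))
    validation_error("every item needs max_level >= 1")
  structure(list(scale_id = scale_id, items = items), class = "symptom_scale")
}

#' @export
print.symptom_scale <- function(x, ...) {
  cat(sprintf("<symptom_scale %s: %d items, levels 0-%d..0-%d>\n",
              x$scale_id, nrow(x$items), min(x$items$max_level),
              max(x$items$max_level)))
  invisible(x)
}

#' Standard 17-item Hamilton Depression Rating Scale
#'
#' Default level structure: nine items scored 0-4 and eight scored 0-2
#' (the conventional HAM-D-17 layout). Items 1-3, 7-11, 15 are the 0-4
#' items.
#'
#' @return A [symptom_scale()] with \code{scale_id = "HAMD17"}.
#' @export
hamd17_scale <- function() {
  labels <- c("depressed mood", "feelings of guilt", "suicide",
              "insomnia: early", "insomnia: middle", "insomnia: late",
              "work and activities", "retardation", "agitation",
              "anxiety psychic", "anxiety somatic",
              "somatic symptoms gastrointestinal", "somatic symptoms general",
              "genital symptoms", "hypochondriasis", "loss of weight",
              "insight")
  max_level <- rep(2L, 17)
  max_level[c(1, 2, 3, 7, 8, 9, 10, 11, 15)] <- 4L
  symptom_scale("HAMD17", data.frame(
    item_id = sprintf("ham_%d", 1:17), label = labels, max_level = max_level))
}

#' Beck Depression Inventory scale (21 items, levels 0-3)
#'
#' @param version \code{"I"} or \code{"II"}.
#' @return A [symptom_scale()] with 21 items scored 0-3.
#' @export
bdi_scale <- function(version = c("II", "I")) {
  version <- match.arg(version)
  labels_ii <- c("sadness", "pessimism", "past failure", "loss of pleasure",
                 "guilty feelings", "punishment feelings", "self-dislike",
                 "self-criticalness", "suicidal thoughts", "crying",
                 "agitation", "loss of interest", "indecisiveness",
                 "worthlessness", "loss of energy", "changes in sleep",
                 "irritability", "changes in appetite",
                 "concentration difficulty", "tiredness or fatigue",
                 "loss of interest in sex")
  symptom_scale(if (version == "I") "BDI_I" else "BDI_II", data.frame(
    item_id = sprintf("bdi_%d", 1:21), label = labels_ii,
    max_level = rep(3L, 21)))
}

#' Read a scale definition from YAML
#'
#' Expected structure:
#' \preformatted{
#' scale_id: HAMD17
#' items:
#'   - {item_id: ham_1, label: depressed mood, max_level: 4}
#'   ...
#' }
#'
#' @param path Path to a YAML file.
#' @return A [symptom_scale()].
#' @export
read_scale_yaml <- function(path) {
  if (!file.exists(path)) validation_error(paste("no such file:", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$scale_id) || is.null(y$items))
    validation_error("scale YAML needs scale_id and items")
  items <- do.call(rbind, lapply(y$items, function(it)
    data.frame(item_id = it$item_id, label = it$label,
               max_level = it$max_level, stringsAsFactors = FALSE)))
  symptom_scale(y$scale_id, items)
}

#' Write a scale definition to YAML
#'
#' @param scale A [symptom_scale()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_scale_yaml <- function(scale, path) {
  stopifnot(inherits(scale, "symptom_scale"))
  y <- list(scale_id = scale$scale_id,
            items = lapply(seq_len(nrow(scale$items)), function(i)
              list(item_id = scale$items$item_id[i],
                   label = scale$items$label[i],
                   max_level = scale$items$max_level[i])))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @keywords internal
scale_item_ids <- function(scale) scale$items$item_id

#' @keywords internal
scale_max_level <- function(scale, item_id) {
  i <- match(item_id, scale$items$item_id)
  if (is.na(i)) validation_error(paste("unknown item:", item_id))
  scale$items$max_level[i]
}
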