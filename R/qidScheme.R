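#' Construct a quasi-identifier scheme
#'
#' @param variables data.frame with columns `name`, `n_categories`,
#'   `utility_class` (`"high_utility"` or `"sensitive"`); an
#'   `ethnicity_group_member` logical column is derived from
#'   `ethnicityVariants` if absent.
#' @param ethnicityVariants character vector of variable names that the
#'   generic ethnicity placeholder expands into during model enumeration
#'   (may be empty for schemes without an ethnicity group).
#' @param genericName name of the placeholder used in enumeration.
#' @return A [QidScheme] object.
#' @examples
#' sch <- qidScheme(data.frame(
#'   name = c("age", "gender", "diagnosis"),
#'   n_categories = c(24L, 2L, 10L),
#'   utility_class = c("high_utility", "high_utility", "sensitive")
#' ))
#' @export
qidScheme <- function(variables, ethnicityVariants = character(),
                      genericName = "ethnicity") {
  variables <- as.data.frame(variables, stringsAsFactors = FALSE)
  if (!"ethnicity_group_member" %in% names(variables)) {
    variables$ethnicity_group_member <- variables$name %in% ethnicityVariants
  }
  variables$n_categories <- as.integer(variables$n_categories)
  new("QidScheme",
      variables = variables,
      ethnicityVariants = as.character(ethnicityVariants),
      genericName = genericName)
}

#' The default census-style quasi-identifier scheme
#'
#' Eleven commonly used demographic quasi-identifiers with their declared
#' response-category counts: gender (2), age in 5-year bands (24), language
#' spoken at home (4), ethnic origin (26), aboriginal identity (8), religious
#' denomination (3), years of schooling (9), marital status (5), total income
#' in $15K bands (22), visible minority status (4) and activity difficulties
#' (4). Age and gender are the high-utility variables; the four
#' ethnicity-related variables (language, ethnic origin, religion, visible
#' minority) form the ethnicity group behind the generic placeholder, giving
#' 8 distinct quasi-identifiers for model enumeration.
#'
#' @return A [QidScheme].
#' @examples
#' defaultQidScheme()
#' @export
defaultQidScheme <- function() {
  vars <- data.frame(
    name = c("gender", "age", "language", "ethnic_origin", "aboriginal",
             "religion", "schooling", "marital", "income",
             "visible_minority", "disability"),
    n_categories = c(2L, 24L, 4L, 26L, 8L, 3L, 9L, 5L, 22L, 4L, 4L),
    utility_class = c("high_utility", "high_utility", rep("sensitive", 9L)),
    stringsAsFactors = FALSE
  )
  qidScheme(vars,
            ethnicityVariants = c("language", "ethnic_origin", "religion",
                                  "visible_minority"))
}

#' Maximum number of equivalence classes of a quasi-identifier model
#'
#' `MaxCombs` is the product of the response-category counts of the model's
#' member variables: the largest number of distinct value combinations — and
#' hence equivalence classes — the model can produce.
#'
#' @param scheme a [QidScheme].
#' @param members character vector of member variable names (length >= 1).
#' @return The product of the members' `n_categories`, as a double (products
#'   can exceed integer range).
#' @examples
#' sch <- defaultQidScheme()
#' maxCombs(sch, c("age", "marital", "schooling", "religion")) # 3240
#' maxCombs(sch, c("gender", "religion"))                      # 6
#' @export
maxCombs <- function(scheme, members) {
  stopifnot(is(scheme, "QidScheme"), length(members) >= 1L)
  v <- scheme@variables
  unknown <- setdiff(members, v$name)
  if (length(unknown)) {
    stop("unknown quasi-identifier(s): ", paste(unknown, collapse = ", "))
  }
  prod(as.numeric(v$n_categories[match(members, v$name)]))
}

#' Distinct quasi-identifiers of a scheme
#'
#' Collapses the ethnicity group to the generic placeholder: the returned
#' names are the non-ethnicity variables plus (if the scheme declares
#' variants) the generic placeholder name.
#'
#' @param scheme a [QidScheme].
#' @return Character vector of distinct quasi-identifier names.
#' @export
distinctQids <- function(scheme) {
  stopifnot(is(scheme, "QidScheme"))
  nm <- setdiff(scheme@variables$name, scheme@ethnicityVariants)
  if (length(scheme@ethnicityVariants)) nm <- c(nm, scheme@genericName)
  nm
}

#' Enumerate quasi-identifier models
#'
#' Enumerates every model of `minSize` to `maxSize` distinct
#' quasi-identifiers that contains at least one high-utility variable, then
#' expands each occurrence of the generic ethnicity placeholder into one
#' concrete model per ethnicity variant. The result is deduplicated and
#' deterministically ordered (by model size, then lexicographic member
#' names). Under the default scheme this yields 358 models.
#'
#' @param scheme a [QidScheme].
#' @param minSize,maxSize model sizes considered (defaults 2 and 5).
#' @return data.frame with columns `model_id`, `size`, `members`
#'   (comma-separated names) and `max_combs`.
#' @examples
#' models <- enumerateModels(defaultQidScheme())
#' nrow(models)          # 358
#' min(models$max_combs) # 6
#' @export
enumerateModels <- function(scheme, minSize = 2L, maxSize = 5L) {
  stopifnot(is(scheme, "QidScheme"), minSize >= 1L, maxSize >= minSize)
  v <- scheme@variables
  generic <- scheme@genericName
  variants <- scheme@ethnicityVariants
  if (length(variants) &&
      !all(variants %in% v$name)) {
    stop("scheme is missing a declared ethnicity variant")
  }
  qids <- distinctQids(scheme)
  highUtility <- v$name[v$utility_class == "high_utility"]

  memberSets <- list()
  for (size in seq(minSize, min(maxSize, length(qids)))) {
    combs <- utils::combn(sort(qids), size, simplify = FALSE)
    keep <- vapply(combs, function(m) any(m %in% highUtility), logical(1))
    memberSets <- c(memberSets, combs[keep])
  }

  # expand the generic placeholder into its concrete variants
  expanded <- list()
  for (m in memberSets) {
    if (generic %in% m) {
      base <- setdiff(m, generic)
      for (variant in variants) {
        expanded[[length(expanded) + 1L]] <- sort(c(base, variant))
      }
    } else {
      expanded[[length(expanded) + 1L]] <- sort(m)
    }
  }

  keys <- vapply(expanded, paste, character(1), collapse = ",")
  expanded <- expanded[!duplicated(keys)]
  sizes <- lengths(expanded)
  keys <- vapply(expanded, paste, character(1), collapse = ",")
  ord <- order(sizes, keys)
  expanded <- expanded[ord]

  data.frame(
    model_id = sprintf("m%03d", seq_along(expanded)),
    size = lengths(expanded),
    members = vapply(expanded, paste, character(1), collapse = ","),
    max_combs = vapply(expanded, function(m) maxCombs(scheme, m), numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Split a comma-separated member string into names
#'
#' @param members a `members` value from [enumerateModels()] output, or a
#'   character vector already holding names.
#' @return Character vector of member names.
#' @export
modelMembers <- function(members) {
  if (length(members) == 1L && grepl(",", members)) {
    members <- strsplit(members, ",", fixed = TRUE)[[1]]
  }
  trimws(members)
}

#' Read / write a quasi-identifier scheme file
#'
#' Scheme files are YAML with a `variables` list (each entry `name`,
#' `n_categories`, `utility_class`) and an `ethnicity_variants` list.
#'
#' @param path file path.
#' @return `readQidScheme()` returns a [QidScheme]; `writeQidScheme()`
#'   invisibly returns `path`.
#' @export
readQidScheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$variables)) stop("scheme file has no 'variables' entry")
  vars <- do.call(rbind, lapply(cfg$variables, function(x) {
    data.frame(name = x$name, n_categories = as.integer(x$n_categories),
               utility_class = x$utility_class, stringsAsFactors = FALSE)
  }))
  qidScheme(vars,
            ethnicityVariants = as.character(unlist(cfg$ethnicity_variants)),
            genericName = if (is.null(cfg$generic_name)) "ethnicity"
                          else cfg$generic_name)
}

#' @rdname readQidScheme
#' @param scheme a [QidScheme] to serialise.
#' @export
writeQidScheme <- function(scheme, path) {
  stopifnot(is(scheme, "QidScheme"))
  v <- scheme@variables
  cfg <- list(
    variables = lapply(seq_len(nrow(v)), function(i) {
      list(name = v$name[i], n_categories = v$n_categories[i],
           utility_class = v$utility_class[i])
    }),
    ethnicity_variants = as.list(scheme@ethnicityVariants),
    generic_name = scheme@genericName
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
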