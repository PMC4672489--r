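# The four-layer hierarchy: user -> experiment -> node -> stream.
# Entities are addressed by their slash-joined path, e.g.
# "csiro-hb/yanco-2013/plot-R1C4/soil-moisture-30cm". Each entity record is
# list(kind, name, parent, attrs, metadata).

ENTITY_KINDS <- c("user", "experiment", "node", "stream")
NAME_RE <- "^[A-Za-z0-9._-]+$"

entityRecord <- function(store, id) {
  rec <- store@env$entities[[id]]
  if (is.null(rec)) stop("no such entity: ", id, call. = FALSE)
  rec
}

entityExists <- function(store, id) !is.null(store@env$entities[[id]])

kindOf <- function(id) ENTITY_KINDS[length(strsplit(id, "/", fixed = TRUE)[[1L]])]

assertKind <- function(store, id, kind) {
  rec <- entityRecord(store, id)
  if (rec$kind != kind)
    stop("expected a ", kind, ": ", id, call. = FALSE)
  rec
}

#' Create a user, experiment, node or stream
#'
#' Builds the hierarchy one entity at a time: users sit at the top,
#' experiments belong to exactly one user (their owner), nodes to exactly
#' one experiment, streams to exactly one node. Names are case-sensitive
#' identifiers (`[A-Za-z0-9._-]+`), unique among the siblings under one
#' parent, and entities are addressed by the slash-joined path of names.
#'
#' Recognised `attrs` by kind: user `description`; experiment `timezone`
#' (IANA-style label, default `"UTC"`, display-only — all storage and
#' window arithmetic is UTC); node `latitude`/`longitude` (decimal
#' degrees); stream `unit` (measurement-unit string, default `""`).
#'
#' @param store a [SensorStore-class].
#' @param kind one of `"user"`, `"experiment"`, `"node"`, `"stream"`.
#' @param name entity name, unique under its parent.
#' @param parent path of the parent entity; `NULL` for users.
#' @param attrs named list of kind-specific attributes (see above).
#' @return The new entity's path, invisibly.
#' @examples
#' store <- SensorStore()
#' createEntity(store, "user", "csiro-hb")
#' createEntity(store, "experiment", "yanco-2013", "csiro-hb")
#' @aliases createEntity
#' @export
setMethod("createEntity", "SensorStore",
          function(store, kind, name, parent = NULL, attrs = list()) {
  kind <- match.arg(kind, ENTITY_KINDS)
  if (!is.character(name) || length(name) != 1L || !grepl(NAME_RE, name))
    stop("invalid name: ", name, call. = FALSE)
  depth <- match(kind, ENTITY_KINDS)
  if (kind == "user") {
    if (!is.null(parent)) stop("hierarchy violation: users have no parent",
                               call. = FALSE)
    id <- name
  } else {
    if (is.null(parent)) stop("no such parent", call. = FALSE)
    if (!entityExists(store, parent))
      stop("no such parent: ", parent, call. = FALSE)
    prec <- entityRecord(store, parent)
    if (prec$kind != ENTITY_KINDS[depth - 1L])
      stop("hierarchy violation: a ", kind, " must sit under a ",
           ENTITY_KINDS[depth - 1L], ", not a ", prec$kind, call. = FALSE)
    id <- paste(parent, name, sep = "/")
  }
  if (entityExists(store, id)) stop("duplicate: ", id, call. = FALSE)
  attrs <- validateAttrs(kind, attrs)
  store@env$entities[[id]] <- list(kind = kind, name = name,
                                   parent = parent, attrs = attrs,
                                   metadata = list())
  if (kind == "stream")
    store@env$streams[[id]] <- list(
      raw = {
        raw <- data.table(t = numeric(0), v = numeric(0))
        setkey(raw, t)
        raw
      },
      agg = sapply(WINDOW_LEVELS, function(l) emptyStatsTable(),
                   simplify = FALSE))
  invisible(id)
})

validateAttrs <- function(kind, attrs) {
  attrs <- as.list(attrs)
  known <- switch(kind,
                  user = "description",
                  experiment = "timezone",
                  node = c("latitude", "longitude"),
                  stream = "unit")
  bad <- setdiff(names(attrs), known)
  if (length(bad))
    stop("unknown attribute(s) for ", kind, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (kind == "experiment" && is.null(attrs$timezone)) attrs$timezone <- "UTC"
  if (kind == "stream" && is.null(attrs$unit)) attrs$unit <- ""
  if (kind == "node") {
    if (xor(is.null(attrs$latitude), is.null(attrs$longitude)))
      stop("latitude and longitude must be given together", call. = FALSE)
    if (!is.null(attrs$latitude)) {
      attrs$latitude <- as.numeric(attrs$latitude)
      attrs$longitude <- as.numeric(attrs$longitude)
      if (is.na(attrs$latitude) || abs(attrs$latitude) > 90)
        stop("latitude out of range [-90, 90]", call. = FALSE)
      if (is.na(attrs$longitude) || abs(attrs$longitude) > 180)
        stop("longitude out of range [-180, 180]", call. = FALSE)
    }
  }
  attrs
}

#' Delete an entity and its whole subtree
#'
#' Deletion cascades: removing a node removes its streams and their raw
#' points and window summaries. (The command-line tool additionally
#' requires an explicit `--force` flag before calling this.)
#'
#' @param store a [SensorStore-class].
#' @param entity path of the entity to delete.
#' @return Invisibly, the paths removed.
#' @aliases deleteEntity
#' @export
setMethod("deleteEntity", "SensorStore", function(store, entity) {
  entityRecord(store, entity)
  ids <- ls(store@env$entities, all.names = TRUE)
  doomed <- c(entity, ids[startsWith(ids, paste0(entity, "/"))])
  rm(list = doomed, envir = store@env$entities)
  gone <- intersect(doomed, ls(store@env$streams, all.names = TRUE))
  if (length(gone)) rm(list = gone, envir = store@env$streams)
  invisible(doomed)
})

#' List the children of an entity
#'
#' @param store a [SensorStore-class].
#' @param parent entity path, or `NULL` to list users.
#' @return Character vector of child paths, sorted by name.
#' @aliases listChildren
#' @export
setMethod("listChildren", "SensorStore", function(store, parent = NULL) {
  ids <- ls(store@env$entities, all.names = TRUE)
  if (is.null(parent)) {
    kids <- ids[!grepl("/", ids, fixed = TRUE)]
  } else {
    entityRecord(store, parent)
    prefix <- paste0(parent, "/")
    kids <- ids[startsWith(ids, prefix) &
                  !grepl("/", substring(ids, nchar(prefix) + 1L),
                         fixed = TRUE)]
  }
  sort(kids)
})

#' Attach metadata to any entity
#'
#' Key/value annotations can sit at every hierarchical layer (trial-level
#' sowing dates on an experiment, treatment labels on a node, sensor depth
#' and type on a stream, ...). Setting an existing key overwrites it.
#'
#' @param store a [SensorStore-class].
#' @param entity entity path.
#' @param key,value metadata key and value (coerced to single strings).
#' @return `setMetadata` returns the store invisibly; `getMetadata` the
#'   named list of the entity's metadata.
#' @rdname setMetadata
#' @aliases setMetadata
#' @export
setMethod("setMetadata", "SensorStore", function(store, entity, key, value) {
  rec <- entityRecord(store, entity)
  stopifnot(is.character(key), length(key) == 1L, nzchar(key))
  rec$metadata[[key]] <- as.character(value)[1L]
  store@env$entities[[entity]] <- rec
  invisible(store)
})

#' @rdname setMetadata
#' @aliases getMetadata
#' @export
setMethod("getMetadata", "SensorStore", function(store, entity) {
  entityRecord(store, entity)$metadata
})

#' Filter a user's streams by name patterns and metadata
#'
#' Selects streams under one user by literal, case-insensitive substring
#' patterns on the experiment / node / stream names and the stream unit,
#' and by metadata predicates `(level, key, value)` that must hold on the
#' stream itself or the ancestor at the stated level (exact, case-sensitive
#' value match). All conditions are conjunctive; with none given, all of
#' the user's streams are returned, ordered by experiment, node, then
#' stream name.
#'
#' @param store a [SensorStore-class].
#' @param user user name.
#' @param experiment,node,stream,unit optional literal substring patterns
#'   (case-insensitive).
#' @param metadata list of predicates, each a list or character vector
#'   `(level, key, value)` with level one of `user`, `experiment`, `node`,
#'   `stream`.
#' @return Character vector of matching stream paths.
#' @examples
#' store <- SensorStore()
#' createEntity(store, "user", "u")
#' createEntity(store, "experiment", "e", "u")
#' createEntity(store, "node", "n", "u/e")
#' createEntity(store, "stream", "temp", "u/e/n", attrs = list(unit = "degC"))
#' filterStreams(store, "u", unit = "degc")
#' @aliases filterStreams
#' @export
setMethod("filterStreams", "SensorStore",
          function(store, user, experiment = NULL, node = NULL,
                   stream = NULL, unit = NULL, metadata = list()) {
  if (!entityExists(store, user) ||
      entityRecord(store, user)$kind != "user")
    stop("no such user: ", user, call. = FALSE)
  for (p in metadata) {
    p <- as.character(unlist(p))
    if (length(p) != 3L || !(p[1L] %in% ENTITY_KINDS))
      stop("bad predicate", call. = FALSE)
  }
  ids <- ls(store@env$entities, all.names = TRUE)
  sids <- ids[startsWith(ids, paste0(user, "/")) &
                vapply(ids, function(i) kindOf(i) == "stream", logical(1))]
  hasSub <- function(hay, needle) {
    grepl(tolower(needle), tolower(hay), fixed = TRUE)
  }
  keep <- vapply(sids, function(sid) {
    parts <- strsplit(sid, "/", fixed = TRUE)[[1L]]
    if (!is.null(experiment) && !hasSub(parts[2L], experiment)) return(FALSE)
    if (!is.null(node) && !hasSub(parts[3L], node)) return(FALSE)
    if (!is.null(stream) && !hasSub(parts[4L], stream)) return(FALSE)
    if (!is.null(unit)) {
      u <- entityRecord(store, sid)$attrs$unit
      if (is.null(u) || !hasSub(u, unit)) return(FALSE)
    }
    for (p in metadata) {
      p <- as.character(unlist(p))
      lvl <- match(p[1L], ENTITY_KINDS)
      anc <- paste(parts[seq_len(lvl)], collapse = "/")
      md <- entityRecord(store, anc)$metadata
      if (is.null(md[[p[2L]]]) || md[[p[2L]]] != p[3L]) return(FALSE)
    }
    TRUE
  }, logical(1))
  found <- sids[keep]
  parts <- strsplit(found, "/", fixed = TRUE)
  ord <- order(vapply(parts, `[`, "", 2L), vapply(parts, `[`, "", 3L),
               vapply(parts, `[`, "", 4L))
  found[ord]
})
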