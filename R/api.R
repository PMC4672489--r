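# RESTful/JSON contract as a request router: method + path + query + body
# in, HTTP-style status + JSON body out. Every read endpoint serialises
# through the same functions the library exposes, so API responses are
# byte-identical to serialising the corresponding library call. (No socket
# server is bundled; any HTTP front-end can delegate to apiRequest.)
#
# Endpoints:
#   GET  /users
#   GET  /users/{u}/experiments             POST {name, timezone?}
#   GET  /users/{u}/experiments/{e}/nodes   POST {name, latitude?, longitude?}
#   GET  /users/{u}/experiments/{e}/nodes/{n}/streams   POST {name, unit?}
#   GET/PUT .../metadata at every level (PUT body: object of key/values)
#   POST /streams/{u}/{e}/{n}/{s}/data      {points: [{t, v}, ...]}
#   GET  /streams/{u}/{e}/{n}/{s}/data?level=...&from=...&to=...
#   GET  /streams/{u}/{e}/{n}/{s}/summary
# Errors: 404 unknown entity, 400 malformed request/range, 409 duplicate
# under the reject policy.

toJson <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

#' Serialise store objects as the API's JSON
#'
#' The canonical JSON renderings used by both the library and the request
#' router — API responses are byte-identical to these.
#'
#' @param store a [SensorStore-class].
#' @param ids entity paths to serialise.
#' @return A JSON string.
#' @export
serializeEntities <- function(store, ids) {
  items <- lapply(ids, function(id) {
    rec <- entityRecord(store, id)
    c(list(name = rec$name, path = id), rec$attrs,
      list(metadata = if (length(rec$metadata)) rec$metadata
           else structure(list(), names = character(0))))
  })
  toJson(items)
}

#' @rdname serializeEntities
#' @param stream stream path.
#' @param level level queried (internal or external spelling).
#' @param tab data.table from [getWindowStats()].
#' @export
serializeWindowStats <- function(stream, level, tab) {
  lvl <- matchLevel(level)
  items <- lapply(seq_len(nrow(tab)), function(i) {
    w <- tab[i]
    list(level = API_LEVEL_NAMES[[lvl]], start = isoTime(w$start),
         count = w$count, mean = w$mean, std = w$std,
         min = w$min, min_time = isoTime(w$min_time),
         max = w$max, max_time = isoTime(w$max_time),
         last = w$last, last_time = isoTime(w$last_time))
  })
  toJson(list(stream = stream, level = API_LEVEL_NAMES[[lvl]],
              windows = items))
}

#' @rdname serializeEntities
#' @param pts data.table from [getRaw()].
#' @export
serializeRaw <- function(stream, pts) {
  items <- lapply(seq_len(nrow(pts)), function(i)
    list(t = isoTime(pts$t[i]), v = pts$v[i]))
  toJson(list(stream = stream, level = "raw", points = items))
}

#' @rdname serializeEntities
#' @param summary data.table from [streamSummary()].
#' @export
serializeSummary <- function(stream, summary) {
  items <- lapply(seq_len(nrow(summary)), function(i) {
    w <- summary[i]
    if (w$count == 0L)
      return(list(level = API_LEVEL_NAMES[[w$level]], count = 0L))
    list(level = API_LEVEL_NAMES[[w$level]], count = w$count,
         mean = w$mean, std = w$std,
         min = w$min, min_time = isoTime(w$min_time),
         max = w$max, max_time = isoTime(w$max_time),
         last = w$last, last_time = isoTime(w$last_time))
  })
  toJson(list(stream = stream, levels = items))
}

apiError <- function(status, message)
  list(status = status, body = toJson(list(error = message)))

apiOk <- function(body, status = 200L) list(status = status, body = body)

#' Handle one API request against a store
#'
#' Routes an HTTP-style request to the corresponding library operation and
#' returns the status code and JSON body an HTTP front-end would send.
#' See the endpoint table in the package sources / README.
#'
#' @param store a [SensorStore-class].
#' @param method `"GET"`, `"POST"` or `"PUT"`.
#' @param path request path, e.g. `"/users/u/experiments"`.
#' @param query named list of query parameters (`level`, `from`, `to`,
#'   `duplicate_policy`).
#' @param body parsed JSON body (named list), or a JSON string.
#' @return list with elements `status` (integer) and `body` (JSON string).
#' @examples
#' store <- SensorStore()
#' apiRequest(store, "POST", "/users", body = list(name = "csiro-hb"))$status
#' @aliases apiRequest
#' @export
setMethod("apiRequest", "SensorStore",
          function(store, method, path, query = list(), body = NULL) {
  if (is.character(body) && length(body) == 1L)
    body <- jsonlite::fromJSON(body, simplifyVector = FALSE)
  seg <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1L]]
  res <- tryCatch(
    routeRequest(store, toupper(method), seg, query, body),
    error = function(e) {
      msg <- conditionMessage(e)
      status <- if (grepl("no such", msg)) 404L
        else if (grepl("duplicate", msg)) 409L
        else 400L
      apiError(status, msg)
    })
  res
})

routeRequest <- function(store, method, seg, query, body) {
  n <- length(seg)
  if (n >= 1L && seg[1L] == "users") {
    # collection endpoints: /users[/{u}/experiments[/{e}/nodes[...]]]
    if (method %in% c("GET", "POST") &&
        (n == 1L || (n %% 2L == 1L &&
                     all(seg[seq(3L, n, by = 2L)] %in%
                         c("experiments", "nodes", "streams"))))) {
      parent <- if (n == 1L) NULL
                else paste(seg[seq(2L, n - 1L, by = 2L)], collapse = "/")
      kind <- ENTITY_KINDS[(n + 1L) %/% 2L]
      if (!is.null(parent)) entityRecord(store, parent)
      if (method == "GET")
        return(apiOk(serializeEntities(store, listChildren(store, parent))))
      if (is.null(body$name)) stop("missing name", call. = FALSE)
      attrs <- body[setdiff(names(body), "name")]
      id <- createEntity(store, kind, body$name, parent, attrs)
      return(apiOk(serializeEntities(store, id), status = 201L))
    }
    # metadata endpoints: /users/{u}[/experiments/{e}[...]]/metadata
    if (seg[n] == "metadata" && n %% 2L == 1L) {
      id <- paste(seg[seq(2L, n - 1L, by = 2L)], collapse = "/")
      if (method == "GET") {
        md <- getMetadata(store, id)
        return(apiOk(toJson(if (length(md)) md
                            else structure(list(), names = character(0)))))
      }
      if (method == "PUT") {
        entityRecord(store, id)
        if (is.null(body) || is.null(names(body)))
          stop("metadata body must be a key/value object", call. = FALSE)
        for (k in names(body)) setMetadata(store, id, k, body[[k]])
        return(apiOk(toJson(getMetadata(store, id))))
      }
    }
  }
  if (n == 6L && seg[1L] == "streams" && seg[6L] %in% c("data", "summary")) {
    sid <- paste(seg[2:5], collapse = "/")
    streamRecord(store, sid)
    if (seg[6L] == "summary" && method == "GET")
      return(apiOk(serializeSummary(sid, streamSummary(store, sid))))
    if (seg[6L] == "data" && method == "POST") {
      pts <- rbindlist(lapply(body$points, function(p)
        data.table(t = parseTime(p$t), v = as.numeric(p$v))))
      policy <- if (is.null(query$duplicate_policy)) "replace"
                else query$duplicate_policy
      rep <- appendPoints(store, sid, pts, duplicatePolicy = policy)
      if (policy == "reject" && rep$rejected > 0L)
        return(apiOk(toJson(list(accepted = rep$accepted,
                                 rejected = rep$rejected,
                                 windows_touched = rep$windows_touched)),
                     status = 409L))
      return(apiOk(toJson(list(accepted = rep$accepted,
                               rejected = rep$rejected,
                               windows_touched = rep$windows_touched)),
                   status = 201L))
    }
    if (seg[6L] == "data" && method == "GET") {
      lvl <- if (is.null(query$level)) "raw" else query$level
      from <- if (is.null(query$from)) 0 else parseTime(query$from)
      to <- if (is.null(query$to)) Inf else parseTime(query$to)
      if (is.na(from) || is.na(to) || from > to)
        stop("malformed range", call. = FALSE)
      if (identical(lvl, "raw"))
        return(apiOk(serializeRaw(sid, getRaw(store, sid, from, to))))
      tab <- getWindowStats(store, sid, lvl, from, to)
      return(apiOk(serializeWindowStats(sid, lvl, tab)))
    }
  }
  stop("no such endpoint: ", paste(seg, collapse = "/"), call. = FALSE)
}
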