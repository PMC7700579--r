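Package: agglomnet
Title: Spatial Correlation Networks of Regional Health-Resource Agglomeration Capacity
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for measuring regional health-resource agglomeration capacity
    with the entropy weight method, inducing a directed spatial correlation
    network from a modified gravity model via mean critical-point binarization,
    characterizing the network (density, level, efficiency, degree, betweenness
    and closeness centrality), partitioning it with CONCOR blockmodeling and a
    four-role spillover typology, and testing covariate association with QAP
    permutation correlation. Includes a synthetic-data generator emulating a
    multi-province panel with an east-to-west capacity gradient so the whole
    pipeline is testable without external yearbook data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
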