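Package: statediagram
Title: State Diagrams of Carbohydrate Food Systems from Thermal
    Transition Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constructs state diagrams of sugar-rich food systems
    (fruit-juice model systems with maltodextrin) from differential
    scanning calorimetry transition temperatures.  Fits the
    Gordon-Taylor glass-transition equation and the Chen
    freezing-point-depression equation to moisture-series data by
    bounded nonlinear least squares, derives the
    maximal-freeze-concentration condition (Tg', Tm', ws') by
    intersecting the averaged onset-of-melting temperature with the
    freezing curve, fits and prunes Scheffe mixture polynomials over a
    six-component D-optimal composition design, and predicts full state
    diagrams for arbitrary juice/maltodextrin compositions.  Includes a
    seeded synthetic-data generator emulating the measurement structure
    of annealed DSC moisture series.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
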