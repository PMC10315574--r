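# colonyscreen

Automated colony picking needs three things from an image of an agar plate:
find every colony, decide which ones are worth picking, and tell the robot
where they are. `colonyscreen` implements that software stack in R as a
hardware-independent library plus a command-line tool, for labs that screen
engineered *E. coli* / *P. putida* clones (blue/white screens, fluorescent
reporters) with a camera over a Petri dish on a liquid handler.

The pipeline is classical image analysis throughout:

1. **Dish detection** — circular Hough voting over a Sobel edge map, refined
   by a Kasa least-squares circle fit, gives the dish centre `O_Pet`, its
   radius, and the pixel offset to the fixed labware centre `O_lab`.
2. **Segmentation** — inside the plate: Gaussian blur + adaptive Gaussian
   thresholding (a pixel is foreground when it exceeds its Gaussian-weighted
   neighbourhood mean), with every component replaced by its convex hull; in
   the wall annulus: speckle-noise injection, Canny-style hysteresis edge
   detection with plastic-border removal, erosion, hole filling and a
   top-hat debris filter. The result is a panoptic-style segment map
   ("colonies" / "0 colonies" / "out of plate") that tiles the crop.
3. **Group splitting** — touching colonies form one segment; regional maxima
   of the smoothed grayscale (minimum separation 0.8 mm) seed a
   marker-controlled watershed that splits the segment into `k` footprints.
4. **Measurement & screening** — per-colony area (mm²), circularly averaged
   HSV colour and mean fluorescence feed a normalized weighted score
   `S = w_size·m_size + w_color·m_color + w_fluor·m_fluor`, each mark in
   [0, 1]; colonies inside the 2 mm wall security margin or below 1 mm
   diameter are flagged unpickable.
5. **Coordinate mapping** — the pixel offset of each selected colony from
   `O_lab` is the vector sum `(c_i − O_Pet′) + (O_Pet − O_lab)`, scaled to
   mm and rotated 90° anticlockwise into the robot frame; the result is a
   picklist CSV the robot consumes.

A synthetic plate generator (dish, agar, Gaussian-dome colonies with
touching groups and border colonies, two colour phenotypes, fluorescence,
uneven illumination, sensor noise, dust specks — with exhaustive ground
truth) makes every stage testable without hardware, and a COCO-panoptic
exporter with 15-fold rotation/mirror augmentation and a source-grouped
75/25 train/validation split reproduces the dataset machinery a learned
detector would train on. The classical detector sits behind a pluggable
interface, so a learned model can replace it without touching the rest.

## Worked example

Pick the 5 colonies most dissimilar from blue (a blue/white screen where
you want the whites) on a simulated 80-colony plate:

```r
library(colonyscreen)

g <- generate_plate(plate_params(n_colonies = 80, seed = 7))
cfg <- run_config(image = g$plate, k = 5,
                  w_size = 0, w_color = 1, w_fluor = 0,
                  target_color = c(110, 130, 212),  # X-gal blue
                  color_mode = "dissimilar",
                  out_dir = "readme_run", verbose = TRUE)
res <- run_pipeline(cfg)
res$picklist
```

```
image: 940 x 940 px
dish r=434.4 px, 83 colony segments
83 footprints, 76 pickable
76 candidates after filtering
picklist: 5 targets -> readme_run/picklist.csv
  colony_id      dx_mm      dy_mm     score pick_order dest_well
1        39  -5.380952 -30.069048 1.0000000          1        A1
2        49   2.099246 -24.175126 0.9785230          2        B1
3        73  26.303719  13.596281 0.9721772          3        C1
4         9 -27.271078   2.386765 0.9599999          4        D1
5        34 -10.077234 -24.011702 0.9597508          5        E1
```

80 true colonies yield 83 footprints (3 dust specks detected alongside);
76 clear the wall margin and size limit. The five selected colonies are the
whitest on the plate — colour score 1.0 is the candidate farthest from the
blue target in HSV cone distance — and `dx_mm`/`dy_mm` are their offsets
from the labware centre in the robot frame, filled into wells column-wise
(A1, B1, …). `readme_run/` also receives `footprints.csv` (every measured
colony), `report.json` (per-stage counts) and `overlay.png` (detections and
selection drawn on the crop).

The same workflow is available from a shell via
`inst/scripts/colonyscreen` with subcommands `simulate`, `detect`, `pick`
(= `screen`), `build-dataset` and `evaluate`, all reading a shared YAML
config with flag overrides.

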