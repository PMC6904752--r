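n_genes: 800
timepoints:
- 0
- 3
- 7
- 21
replicates_per_timepoint: 2
cells_per_replicate: 500
composition:
  msc:
    '0': 0.24
    '3': 0.28
    '7': 0.32
    '21': 0.28
  satellite:
    '0': 0.1
    '3': 0.08
    '7': 0.08
    '21': 0.1
  schwann:
    '0': 0.1
    '3': 0.08
    '7': 0.08
    '21': 0.08
  myofibroblast:
    '0': 0.14
    '3': 0.1
    '7': 0.1
    '21': 0.12
  endothelial:
    '0': 0.15
    '3': 0.1
    '7': 0.1
    '21': 0.14
  lymphocyte:
    '0': 0.1
    '3': 0.1
    '7': 0.08
    '21': 0.1
  myeloid:
    '0': 0.17
    '3': 0.26
    '7': 0.24
    '21': 0.18
composition_days:
- '0'
- '3'
- '7'
- '21'
depth_mean: 5000.0
depth_dispersion: 0.3
nb_dispersion: 0.5
batch_effect_sd: 0.1
mito_fraction_range:
- 0.02
- 0.08
n_mito: 10
exact: no
allow_shared_markers: no
seed: 1
families:
  msc:
    name: msc
    markers:
    - Pdgfra
    - Prrx1
    - msc.m01
    - msc.m02
    - msc.m03
    - msc.m04
    - msc.m05
    - msc.m06
    - msc.m07
    - msc.m08
    - msc.m09
    - msc.m10
    - msc.m11
    - msc.m12
    - msc.m13
    - msc.m14
    marker_fold: 5.0
    subtypes:
      programs:
        tenocyte:
        - Scx
        - Col1a1
        MSC: Pdgfra
        chondrocyte:
        - Sox9
        - Acan
        - Col1a1
        - Col3a1
        preosteoblast:
        - Runx2
        - Col1a1
      weights:
        tenocyte:
          '0': 0.4
          '3': 0.15
          '7': 0.118
          '21': 0.13
        MSC:
          '0': 0.5
          '3': 0.55
          '7': 0.477
          '21': 0.4
        chondrocyte:
          '0': 0.02
          '3': 0.1
          '7': 0.098
          '21': 0.12
        preosteoblast:
          '0': 0.08
          '3': 0.2
          '7': 0.307
          '21': 0.35
      vegfa:
        tenocyte:
          '0': 1.0
          '3': 0.8
          '7': 0.1
          '21': 0.1
        MSC:
          '0': 0.5
          '3': 3.0
          '7': 0.8
          '21': 0.5
        chondrocyte:
          '0': 0.3
          '3': 1.5
          '7': 0.5
          '21': 0.3
        preosteoblast:
          '0': 0.3
          '3': 1.5
          '7': 1.5
          '21': 1.5
      days:
      - '0'
      - '3'
      - '7'
      - '21'
      program_level: 2.0
  satellite:
    name: satellite
    markers:
    - Pax7
    - satellite.m01
    - satellite.m02
    - satellite.m03
    - satellite.m04
    - satellite.m05
    - satellite.m06
    - satellite.m07
    - satellite.m08
    - satellite.m09
    - satellite.m10
    - satellite.m11
    - satellite.m12
    - satellite.m13
    - satellite.m14
    - satellite.m15
    marker_fold: 5.0
  schwann:
    name: schwann
    markers:
    - Plp1
    - Cnp
    - Dhh
    - schwann.m01
    - schwann.m02
    - schwann.m03
    - schwann.m04
    - schwann.m05
    - schwann.m06
    - schwann.m07
    - schwann.m08
    - schwann.m09
    - schwann.m10
    - schwann.m11
    - schwann.m12
    - schwann.m13
    marker_fold: 5.0
  myofibroblast:
    name: myofibroblast
    markers:
    - Acta2
    - Mylk
    - myofibroblast.m01
    - myofibroblast.m02
    - myofibroblast.m03
    - myofibroblast.m04
    - myofibroblast.m05
    - myofibroblast.m06
    - myofibroblast.m07
    - myofibroblast.m08
    - myofibroblast.m09
    - myofibroblast.m10
    - myofibroblast.m11
    - myofibroblast.m12
    - myofibroblast.m13
    - myofibroblast.m14
    marker_fold: 5.0
  endothelial:
    name: endothelial
    markers:
    - Cdh5
    - Pecam1
    - Cd34
    - endothelial.m01
    - endothelial.m02
    - endothelial.m03
    - endothelial.m04
    - endothelial.m05
    - endothelial.m06
    - endothelial.m07
    - endothelial.m08
    - endothelial.m09
    - endothelial.m10
    - endothelial.m11
    - endothelial.m12
    - endothelial.m13
    marker_fold: 5.0
  lymphocyte:
    name: lymphocyte
    markers:
    - Ms4a1
    - lymphocyte.m01
    - lymphocyte.m02
    - lymphocyte.m03
    - lymphocyte.m04
    - lymphocyte.m05
    - lymphocyte.m06
    - lymphocyte.m07
    - lymphocyte.m08
    - lymphocyte.m09
    - lymphocyte.m10
    - lymphocyte.m11
    - lymphocyte.m12
    - lymphocyte.m13
    - lymphocyte.m14
    - lymphocyte.m15
    marker_fold: 5.0
  myeloid:
    name: myeloid
    markers:
    - Ccr2
    - Mrc1
    - Fcgr1
    - Ccr1
    - S100a9
    - Cd209a
    - myeloid.m01
    - myeloid.m02
    - myeloid.m03
    - myeloid.m04
    - myeloid.m05
    - myeloid.m06
    - myeloid.m07
    - myeloid.m08
    - myeloid.m09
    - myeloid.m10
    marker_fold: 5.0
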