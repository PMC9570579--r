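{
  "species_name": "methanethiolate-like (synthetic)",
  "total_charge": -1,
  "atoms": [
    {
      "label": "C",
      "element": "C",
      "position": [0.072011358911109463, -0.084740458243576192, -0.078546137055279422],
      "is_acidic_proton": false
    },
    {
      "label": "S",
      "element": "S",
      "position": [-0.093867661804199282, 0.022236379036468908, 0.0074326356190439723],
      "is_acidic_proton": false
    },
    {
      "label": "H",
      "element": "H",
      "position": [-0.071798828905052153, 0.059958873470504236, -0.0042227516440906561],
      "is_acidic_proton": false
    },
    {
      "label": "H1",
      "element": "H",
      "position": [-0.1155601120221935, 0.019326602933294534, -0.0064262318831556286],
      "is_acidic_proton": false
    },
    {
      "label": "H2",
      "element": "H",
      "position": [-0.026481086268371562, 0.080494856277026752, -0.05232829337842701],
      "is_acidic_proton": false
    }
  ],
  "states": [
    {
      "index": 0,
      "energy0": 0,
      "atomic_charges": [-0.2552610059616694, -0.34538613276995206, -0.29794144335363859, -0.022922368956219075, -0.078489048958520755]
    },
    {
      "index": 1,
      "energy0": 453.96770819650828,
      "atomic_charges": [-0.33911175953299488, -0.62652810227527533, -0.01498316512387262, 0.26503023148681892, -0.28440720455467611]
    },
    {
      "index": 2,
      "energy0": 805.11531568429973,
      "atomic_charges": [-0.58662103725784664, 0.045196278021518932, -0.32149978278515007, 0.059938884787002045, -0.19701434276552426]
    },
    {
      "index": 3,
      "energy0": 1154.0151630758728,
      "atomic_charges": [-0.44595909633409664, -0.30387213015914877, -0.27989959109734353, -0.4466678363389755, 0.47639865392956443]
    },
    {
      "index": 4,
      "energy0": 1512.5859664563159,
      "atomic_charges": [-0.34621107478730306, 0.33862848301942561, -0.48645233303366592, -0.55661335224473207, 0.050648277046275447]
    },
    {
      "index": 5,
      "energy0": 2014.9389066150811,
      "atomic_charges": [-0.54351166631189529, -0.43506723168702688, 0.065957566335342194, -0.00018514892895422214, -0.087193519407465767]
    },
    {
      "index": 6,
      "energy0": 2410.7933508453466,
      "atomic_charges": [-0.37842280129687111, -0.36541391250644584, -0.36368984742478105, 0.14311432766480317, -0.035587766436705109]
    }
  ],
  "dipoles": [
    {
      "i": 0,
      "j": 0,
      "vector": [0.20738197038346576, -0.087480384047637, -0.029689511370263228]
    },
    {
      "i": 0,
      "j": 1,
      "vector": [-0.090484421793410846, -0.16329726012839224, 0.02758729109190728]
    },
    {
      "i": 0,
      "j": 2,
      "vector": [0.19607044421490571, -0.025242493594401446, 0.05157611217507637]
    },
    {
      "i": 0,
      "j": 3,
      "vector": [0.056471184269447548, -0.029180941357075097, -0.31730040352380501]
    },
    {
      "i": 0,
      "j": 4,
      "vector": [-0.1369601102893967, 0.052456387822650156, 0.06083656621524719]
    },
    {
      "i": 0,
      "j": 5,
      "vector": [0.075798918528654738, -0.2687800659673828, -0.099223340310859262]
    },
    {
      "i": 0,
      "j": 6,
      "vector": [-0.055840926819598562, 0.02379915128153853, -0.10176186237747251]
    },
    {
      "i": 1,
      "j": 1,
      "vector": [0.012373354166881057, 0.1865610163917272, 0.13207433222272691]
    },
    {
      "i": 1,
      "j": 2,
      "vector": [0.081593809125680511, -0.11863576901014078, 0.064071704487786166]
    },
    {
      "i": 1,
      "j": 3,
      "vector": [0.14266714755180268, 0.12301756356898301, -0.27164189558130142]
    },
    {
      "i": 1,
      "j": 4,
      "vector": [-0.041987045518523433, 0.10066023842214236, 0.23954587963091925]
    },
    {
      "i": 1,
      "j": 5,
      "vector": [-0.10885977430143394, 0.14408627487643835, 0.14346593774334654]
    },
    {
      "i": 1,
      "j": 6,
      "vector": [0.18987715300266012, -0.035543425991823828, -0.2280171114645719]
    },
    {
      "i": 2,
      "j": 2,
      "vector": [0.050933013791461361, 0.20939608667216078, -0.17790933350659455]
    },
    {
      "i": 2,
      "j": 3,
      "vector": [-0.060670732431800788, -0.04306592243083205, 0.14138786225048042]
    },
    {
      "i": 2,
      "j": 4,
      "vector": [-0.15821078850104178, -0.098591626506398244, -0.062143330574187541]
    },
    {
      "i": 2,
      "j": 5,
      "vector": [0.06809500402716212, -0.083093095910263925, 0.053080279238904453]
    },
    {
      "i": 2,
      "j": 6,
      "vector": [0.022242872518763872, 0.056476787300771832, 0.2260480655829824]
    },
    {
      "i": 3,
      "j": 3,
      "vector": [-0.13909424276157425, -0.088071184615231099, 0.36883885645684661]
    },
    {
      "i": 3,
      "j": 4,
      "vector": [0.10106128214287229, 0.050163655048085475, 0.24135629048129345]
    },
    {
      "i": 3,
      "j": 5,
      "vector": [-0.16730988869154151, 0.0015195105146754509, -0.15785369050263884]
    },
    {
      "i": 3,
      "j": 6,
      "vector": [0.065088485952976671, 0.09871344257968119, -0.21601099960956194]
    },
    {
      "i": 4,
      "j": 4,
      "vector": [0.071004181343496495, -0.12087781767220646, -0.11781988886605194]
    },
    {
      "i": 4,
      "j": 5,
      "vector": [-0.17030259035427953, -0.13671377648553984, 0.013494940907559656]
    },
    {
      "i": 4,
      "j": 6,
      "vector": [-0.035414211555845121, 0.24413686840769883, 0.075780094129705738]
    },
    {
      "i": 5,
      "j": 5,
      "vector": [0.0056155953159794311, 0.054774781526886418, -0.20919012024179559]
    },
    {
      "i": 5,
      "j": 6,
      "vector": [0.095270198257331254, -0.071662904664972479, -0.12299613814621337]
    },
    {
      "i": 6,
      "j": 6,
      "vector": [0.1878576232982227, -0.19775249190633032, 0.081639177116035827]
    }
  ]
}
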