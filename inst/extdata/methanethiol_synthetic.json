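{
  "species_name": "methanethiol-like (synthetic)",
  "total_charge": 0,
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
    },
    {
      "label": "H3",
      "element": "H",
      "position": [-0.23205031899536493, -0.014811682017841067, -0.076054680726366522],
      "is_acidic_proton": true
    }
  ],
  "states": [
    {
      "index": 0,
      "energy0": 0,
      "atomic_charges": [-0.12699112433581525, 0.22696205008758283, 0.02460037806764959, -0.26038823438439107, 0.033532154800808511, 0.10228477576416541]
    },
    {
      "index": 1,
      "energy0": 531.56494102497436,
      "atomic_charges": [-0.14051494954138027, -0.35032459107046471, 0.066735005087184787, 0.21943386416155744, 0.48885230396905932, -0.28418163260595652]
    },
    {
      "index": 2,
      "energy0": 1050.2886540129098,
      "atomic_charges": [0.24908814350642788, -0.01207573354160834, -0.026631320455034448, -0.02376063167308954, 0.14689197646453703, -0.33351243430123256]
    },
    {
      "index": 3,
      "energy0": 1529.4455167168389,
      "atomic_charges": [0.13139632979024002, -0.21217973835892268, 0.275309116336455, -0.3584760035132778, 0.22369396931876886, -0.05974367357326342]
    },
    {
      "index": 4,
      "energy0": 2010.1375967616407,
      "atomic_charges": [-0.15447809378383326, 0.32390911052622318, -0.33650929356047909, 0.11135791055949114, 0.0078608603737022505, 0.047859505884895751]
    },
    {
      "index": 5,
      "energy0": 2549.2100541450382,
      "atomic_charges": [-0.1440461797866095, 0.25154766617420249, -0.501587941625115, 0.43560546994716964, 0.28100754580334503, -0.32252656051299278]
    },
    {
      "index": 6,
      "energy0": 3096.1308371238101,
      "atomic_charges": [-0.0065665823152508615, 0.00073819266913118659, -0.023793235510966456, 0.25685086764805243, -0.17796421873204404, -0.049265023758922236]
    }
  ],
  "dipoles": [
    {
      "i": 0,
      "j": 0,
      "vector": [-0.1706027327589027, 0.16080813712848788, 0.34717478726870804]
    },
    {
      "i": 0,
      "j": 1,
      "vector": [0.063445965749359595, -0.020540857082814386, 0.19925947851971978]
    },
    {
      "i": 0,
      "j": 2,
      "vector": [0.065480349810351363, 0.0099642771418880626, 0.19569897144223317]
    },
    {
      "i": 0,
      "j": 3,
      "vector": [-0.031388930866477732, 0.15273795559081951, 0.2049052443997233]
    },
    {
      "i": 0,
      "j": 4,
      "vector": [0.22150437733470302, 0.13309597968146261, -0.1523863349311895]
    },
    {
      "i": 0,
      "j": 5,
      "vector": [0.28063035916319301, 0.16142976295179653, -0.16116114432440393]
    },
    {
      "i": 0,
      "j": 6,
      "vector": [-0.32933639603251086, 0.080181685284157603, 0.20156001441105645]
    },
    {
      "i": 1,
      "j": 1,
      "vector": [0.20775053117757036, 0.41203901630401452, -0.0068917032741825828]
    },
    {
      "i": 1,
      "j": 2,
      "vector": [0.11146280088475109, 0.039063704295812192, 0.064242285577337369]
    },
    {
      "i": 1,
      "j": 3,
      "vector": [-0.055238813089098164, 0.43311349553035317, -0.091060896571830169]
    },
    {
      "i": 1,
      "j": 4,
      "vector": [-0.28187981051094102, 0.10775348530494663, 0.037713835348451095]
    },
    {
      "i": 1,
      "j": 5,
      "vector": [0.070053445971266087, -0.032683257060990401, -0.18264715608283294]
    },
    {
      "i": 1,
      "j": 6,
      "vector": [-0.11311177579570168, 0.028684527113212292, 0.15709241470201576]
    },
    {
      "i": 2,
      "j": 2,
      "vector": [0.16347425776421873, 0.10432116290194454, -0.078655313473086061]
    },
    {
      "i": 2,
      "j": 3,
      "vector": [0.039602389376359466, 0.18618005896151874, 0.096494585824800874]
    },
    {
      "i": 2,
      "j": 4,
      "vector": [-0.14951439138038672, -0.3003447681638497, -0.07137586604113498]
    },
    {
      "i": 2,
      "j": 5,
      "vector": [0.0066269972845309716, -0.20717030376776283, 0.037127948192368004]
    },
    {
      "i": 2,
      "j": 6,
      "vector": [0.033628447549058769, 0.12922184160004702, -0.13901433969160754]
    },
    {
      "i": 3,
      "j": 3,
      "vector": [-0.048066450716810205, 0.10095371652335734, -0.18984446354754031]
    },
    {
      "i": 3,
      "j": 4,
      "vector": [-0.077778144375860211, 0.16837411883572256, -0.047396630331471172]
    },
    {
      "i": 3,
      "j": 5,
      "vector": [-0.26374488053614026, 0.18558801574427689, -0.24959285536988945]
    },
    {
      "i": 3,
      "j": 6,
      "vector": [0.27836016847010292, 0.15869961221546658, 0.0055903224796780455]
    },
    {
      "i": 4,
      "j": 4,
      "vector": [0.00069075341739493362, -0.29157514098792103, -0.23544351148926293]
    },
    {
      "i": 4,
      "j": 5,
      "vector": [-0.040994573920762924, 0.070328072962273294, 0.15488081431077078]
    },
    {
      "i": 4,
      "j": 6,
      "vector": [-0.21275941563484421, -0.013181625411354647, 0.23679461222264173]
    },
    {
      "i": 5,
      "j": 5,
      "vector": [0.036693739862555426, 0.22456402462204816, 0.13738596283424867]
    },
    {
      "i": 5,
      "j": 6,
      "vector": [0.048126178677370977, 0.084408641183530364, 0.080894297690526015]
    },
    {
      "i": 6,
      "j": 6,
      "vector": [-0.16101073669982685, -0.28247409426081649, 0.13670853009994519]
    }
  ]
}
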