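{
  "translation_tol": 4,
  "rotation_tol": 25,
  "entries": [
    {
      "rotation": [
        [-0.573576436351045, 0.340997261978349, -0.744802617467275],
        [0.689325277321726, -0.290279442457974, -0.663753348263957],
        [-0.442538962926611, -0.894124550948891, -0.0685605840281613]
      ],
      "translation": [4.96650042770712, 11.4476050960559, -7.34923185594645]
    }
  ],
  "provenance": [
    {
      "source": "synthetic-kturn",
      "c_pair1": "A:2|B:7",
      "c_pair2": "A:3|B:6",
      "nc_pair1": "A:9|B:3",
      "nc_pair2": "A:10|B:2"
    }
  ]
}
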