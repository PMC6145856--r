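"name","network","x","y","z","radius"
"DMN.aMPFC","default_mode",-1,49,-2,6
"DMN.PCC","default_mode",-1,-52,26,6
"DMN.L.LatParietal","default_mode",-46,-66,30,6
"DMN.R.LatParietal","default_mode",49,-63,33,6
"ExecuContr.DMPFC","executive_control",0,24,46,6
"ExecuContr.L.antPFC","executive_control",-44,45,0,6
"ExecuContr.R.antPFC","executive_control",44,45,0,6
"ExecuContr.L.SupParietal","executive_control",-50,-51,45,6
"ExecuContr.R.SupParietal","executive_control",50,-51,45,6
"Salience.dACC","salience",-2,14,28,6
"Salience.L.antInsula","salience",-40,18,-2,6
"Salience.R.antInsula","salience",42,10,-12,6
"Salience.R.dlPFC","salience",32,45,30,6
"Sensorimotor.L.M1","sensorimotor",-39,-26,51,6
"Sensorimotor.R.M1","sensorimotor",38,-26,51,6
"Sensorimotor.SMA","sensorimotor",0,-21,48,6
"Auditory.L.A1","auditory",-54,-14,8,6
"Auditory.R.A1","auditory",54,-14,8,6
"Auditory.MCC","auditory",0,-8,40,6
"Visual.L.V1","visual",-10,-83,3,6
"Visual.R.V1","visual",13,-80,6,6
"Visual.Extrastriate","visual",0,-93,20,6
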