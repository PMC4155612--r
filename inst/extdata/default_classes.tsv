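accession	class
KYTJ820101	hydrophobicity
HOPT810101	hydrophobicity
EISD840101	hydrophobicity
FAUJ830101	hydrophobicity
PRAM900101	hydrophobicity
ARGP820101	hydrophobicity
MIYS850101	hydrophobicity
PONP800101	hydrophobicity
ROSM880102	hydrophobicity
WOLR810101	hydrophobicity
BULH740101	hydrophobicity
CHOP780201	alpha_turn_propensity
CHOP780203	alpha_turn_propensity
LEVM780101	alpha_turn_propensity
LEVM780103	alpha_turn_propensity
PRAM900102	alpha_turn_propensity
PRAM900104	alpha_turn_propensity
ROBB760101	alpha_turn_propensity
ROBB760113	alpha_turn_propensity
QIAN880106	alpha_turn_propensity
CHOP780202	beta_propensity
LEVM780102	beta_propensity
PRAM900103	beta_propensity
QIAN880119	beta_propensity
GRAR740101	composition
DAYM780101	composition
JUNJ780101	composition
NAKH900101	composition
CEDJ970101	composition
JOND920101	composition
FASG760101	composition
GRAR740102	physicochemical
GRAR740103	physicochemical
ZIMJ680102	physicochemical
ZIMJ680103	physicochemical
ZIMJ680104	physicochemical
BIGC670101	physicochemical
GOLD730102	physicochemical
JOND750102	physicochemical
CHAM820101	physicochemical
BHAR880101	physicochemical
FAUJ880103	physicochemical
RADA880108	physicochemical
KRIW790101	physicochemical
JANJ780101	other
CHOC760101	other
CHOC760102	other
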