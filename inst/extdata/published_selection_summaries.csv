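model,response,term,P,BF,BF_bound
colour_reward,lipid,x,0.31,-1.6,FALSE
colour_reward,lipid,y,0.29,-1.8,FALSE
colour_reward,lipid,z,0.27,-2.0,FALSE
colour_reward,lipid,a,0.95,6.0,FALSE
colour_reward,sugar,x,0.33,-1.4,FALSE
colour_reward,sugar,y,0.29,-1.8,FALSE
colour_reward,sugar,z,0.31,-1.6,FALSE
colour_reward,sugar,a,0.77,2.5,FALSE
colour_reward,protein,x,0.34,-1.4,FALSE
colour_reward,protein,y,0.37,-1.1,FALSE
colour_reward,protein,z,0.36,-1.2,FALSE
colour_reward,protein,a,0.32,-1.5,FALSE
colour_reward,anthocyanin,x,0.44,-0.44,FALSE
colour_reward,anthocyanin,y,0.68,1.5,FALSE
colour_reward,anthocyanin,z,0.57,0.60,FALSE
colour_reward,anthocyanin,a,0.97,6.8,FALSE
sem,x,partner_diversity,0.20,-2.7,FALSE
sem,x,interaction_strength,0.20,-2.8,FALSE
sem,x,migratory_distance,0.25,-2.2,FALSE
sem,y,partner_diversity,0.61,0.87,FALSE
sem,y,interaction_strength,0.22,-2.5,FALSE
sem,y,migratory_distance,0.50,0.0080,FALSE
sem,z,partner_diversity,0.19,-2.9,FALSE
sem,z,interaction_strength,0.23,-2.5,FALSE
sem,z,migratory_distance,0.70,1.7,FALSE
sem,a,partner_diversity,1.0,15,TRUE
sem,a,interaction_strength,0.22,-2.5,FALSE
sem,a,migratory_distance,0.97,7.1,FALSE
sem,lipid,partner_diversity,0.35,-1.3,FALSE
sem,lipid,interaction_strength,0.60,0.80,FALSE
sem,lipid,migratory_distance,0.19,-2.8,FALSE
sem,lipid,x,0.19,-2.9,FALSE
sem,lipid,y,0.98,7.9,FALSE
sem,lipid,z,0.22,-2.5,FALSE
sem,lipid,a,1.0,15,TRUE
sem,sugar,partner_diversity,0.37,-1.0,FALSE
sem,sugar,interaction_strength,0.30,-1.7,FALSE
sem,sugar,migratory_distance,0.22,-2.5,FALSE
sem,sugar,x,0.50,-0.036,FALSE
sem,sugar,y,0.46,-0.34,FALSE
sem,sugar,z,0.38,-0.99,FALSE
sem,sugar,a,1.0,14,FALSE
sem,protein,partner_diversity,0.33,-1.5,FALSE
sem,protein,interaction_strength,0.19,-2.9,FALSE
sem,protein,migratory_distance,0.19,-2.9,FALSE
sem,protein,x,0.53,0.25,FALSE
sem,protein,y,0.99,8.6,FALSE
sem,protein,z,0.36,-1.1,FALSE
sem,protein,a,0.28,-1.9,FALSE
sem,anthocyanin,partner_diversity,0.72,1.9,FALSE
sem,anthocyanin,interaction_strength,0.23,-2.5,FALSE
sem,anthocyanin,migratory_distance,0.13,-3.7,FALSE
sem,anthocyanin,x,0.99,8.6,FALSE
sem,anthocyanin,y,1.0,15,TRUE
sem,anthocyanin,z,1.0,15,TRUE
sem,anthocyanin,a,1.0,15,TRUE
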