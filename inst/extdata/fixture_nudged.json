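{"format":"nudgenet-session","version":"1","header":{"n_players":25,"inquiry_cost":1,"reply_cost":1,"reward":10,"endowment":100,"label":"FN25","nudged":true,"suggestion_rounds":5,"seed":202,"n_rounds":6},"rounds":[{"round":1,"assignment":{"player_order":[16,14,8,23,6,25,4,13,22,1,18,17,11,5,15,9,10,24,21,3,12,19,7,2,20],"letter_order":["Q","F","M","H","P","G","A","S","D","J","C","L","K","W","O","X","B","U","R","I","N","T","Y","V","E"],"question":["J","V","I","A","W","P","Y","M","X","B","K","N","S","F","O","Q","L","C","T","E","R","D","H","U","G"],"expertise":["C","E","N","S","O","G","V","H","B","U","W","T","D","M","X","F","K","L","Y","Q","I","J","P","R","A"]},"inquiries":{"sender":[1,1,2,2,2,2,3,3,4,4,4,4,5,5,5,5,6,6,6,6,6,7,7,7,7,8,8,8,8,8,9,9,9,9,10,10,10,10,11,12,12,13,13,13,14,14,15,15,15,15,16,16,17,17,17,18,18,18,19,19,20,20,20,20,20,20,21,21,22,23,23,23,24,24,24,24,24,24,25,25,25],"receiver":[24,7,3,12,21,9,19,4,3,22,13,5,18,4,16,25,10,7,3,25,1,6,1,22,17,11,4,7,24,20,10,8,18,13,23,15,6,16,17,11,6,25,16,14,23,13,20,3,14,10,22,13,18,11,8,19,14,5,3,20,8,19,15,25,10,16,16,9,12,1,22,24,3,23,17,8,25,11,21,24,6]},"replies":{"sender":[1,6,10,13,17,18,23,24,24],"receiver":[6,25,9,14,11,17,24,8,23],"kind":["referral","self_expert","referral","referral","self_expert","self_expert","referral","uninformed","referral"],"named_player":[23,null,15,16,null,null,10,null,8]}},{"round":2,"assignment":{"player_order":[12,23,22,1,14,4,8,24,3,10,17,6,13,21,2,25,20,19,7,18,16,15,5,11,9],"letter_order":["K","D","J","U","T","R","G","B","C","I","F","V","E","O","X","Y","L","S","M","P","N","A","Q","H","W"],"question":["U","X","C","R","Q","V","M","G","W","I","H","K","E","T","A","N","F","P","S","L","O","J","D","B","Y"],"expertise":["T","Y","I","G","H","E","P","B","K","F","W","D","O","R","Q","A","V","N","M","S","X","U","J","C","L"]},"inquiries":{"sender":[1,1,1,1,1,1,2,3,3,3,3,3,4,4,4,5,5,6,6,6,7,7,8,9,9,9,9,10,10,10,10,11,11,11,12,12,13,13,13,13,13,14,14,15,15,16,16,17,17,18,18,18,18,18,18,18,18,19,19,19,19,20,20,20,21,21,21,21,21,21,22,22,22,23,23,23,24,24,25,25,25,25],"receiver":[23,2,5,7,20,14,21,2,4,6,23,12,13,3,24,10,25,7,19,10,1,14,17,21,2,13,18,9,5,6,15,12,17,15,11,22,12,4,16,14,9,7,15,25,14,4,13,11,7,9,19,5,17,8,21,14,13,20,6,23,18,19,8,25,9,15,25,18,22,2,12,11,21,10,14,22,23,3,6,20,5,13]},"replies":{"sender":[4,6,7,7,9,13,14,20,21,22,25,25,25],"receiver":[3,10,6,14,21,16,18,19,2,23,5,20,21],"kind":["uninformed","referral","referral","referral","referral","referral","referral","self_expert","self_expert","referral","referral","self_expert","uninformed"],"named_player":[null,3,17,1,13,18,7,null,null,12,15,null,null]}},{"round":3,"assignment":{"player_order":[24,1,18,8,14,6,4,23,15,13,10,2,25,17,11,3,20,9,7,16,5,21,22,19,12],"letter_order":["T","F","P","N","G","E","V","B","A","S","U","L","Q","C","I","J","W","H","M","K","R","Y","O","X","D"],"question":["F","L","J","V","R","E","M","N","H","U","I","D","S","G","A","K","C","P","X","W","Y","O","B","T","Q"],"expertise":["P","Q","W","B","Y","V","K","G","M","L","J","T","U","E","S","R","I","N","D","H","O","X","A","F","C"]},"inquiries":{"sender":[1,1,1,1,1,2,3,4,4,4,4,5,5,5,5,5,5,5,6,6,7,7,7,7,7,8,8,8,9,9,11,11,11,11,11,12,12,12,13,13,13,13,13,13,13,13,13,13,14,14,14,14,14,14,14,15,15,15,15,16,16,16,16,17,17,18,18,18,18,19,19,19,19,20,20,20,21,21,22,23,23,24,24,24,25,25,25],"receiver":[7,5,23,15,2,13,4,13,3,2,5,25,1,10,11,18,4,13,3,25,6,17,1,8,22,20,9,3,10,18,12,24,17,5,8,22,13,6,2,9,4,16,14,25,12,24,7,19,23,1,18,13,7,5,4,10,3,11,20,20,13,25,17,11,7,21,17,19,5,18,6,20,23,25,19,1,18,25,23,24,1,23,8,3,21,6,20]},"replies":{"sender":[3,4,5,6,8,9,13,17,19,23,23,25],"receiver":[4,13,18,12,11,13,5,16,18,1,19,5],"kind":["referral","uninformed","referral","referral","uninformed","uninformed","referral","referral","uninformed","referral","referral","referral"],"named_player":[6,null,1,19,null,null,16,7,null,24,22,16]}},{"round":4,"assignment":{"player_order":[19,18,15,16,2,9,5,21,17,22,4,6,23,20,11,25,13,1,10,24,12,14,7,8,3],"letter_order":["P","E","X","I","L","N","D","B","R","O","H","V","C","A","W","F","T","Q","M","Y","G","J","U","S","K"],"question":["Q","L","K","H","D","V","U","S","N","M","W","G","T","J","X","I","R","E","P","A","B","O","C","Y","F"],"expertise":["M","N","P","V","B","C","S","K","D","Y","F","J","Q","U","I","L","O","X","E","W","R","H","A","G","T"]},"inquiries":{"sender":[1,1,3,3,3,3,4,4,4,5,6,6,6,6,7,7,8,8,8,9,9,9,9,9,10,10,10,11,11,11,11,11,12,12,12,12,13,13,13,13,13,13,14,14,14,15,16,16,16,16,16,17,17,17,17,17,17,17,18,18,18,19,19,19,19,20,20,21,21,21,21,22,22,22,24,25],"receiver":[23,5,4,6,24,19,3,13,8,25,10,7,25,19,17,14,24,11,20,8,13,10,21,18,23,5,3,5,12,24,15,8,22,6,2,13,4,9,16,14,25,12,13,15,18,10,23,13,4,20,17,18,7,11,16,2,24,12,9,5,19,18,20,12,6,1,16,9,18,2,25,23,12,21,17,5]},"replies":{"sender":[2,5,5,6,12,13,14,18,19,23,24,25],"receiver":[17,10,25,19,22,14,7,17,18,10,3,21],"kind":["referral","referral","referral","referral","referral","referral","self_expert","referral","self_expert","referral","referral","referral"],"named_player":[21,1,11,3,17,12,null,21,null,1,8,5]}},{"round":5,"assignment":{"player_order":[7,11,17,9,12,20,25,13,6,2,14,3,23,16,15,22,18,24,8,1,21,4,19,10,5],"letter_order":["W","J","T","N","V","M","E","L","D","P","I","F","Y","H","A","C","O","K","S","U","X","B","Q","G","R"],"question":["U","P","F","B","R","D","W","S","N","G","J","V","L","I","A","H","T","O","Q","M","X","C","Y","K","E"],"expertise":["X","I","Y","Q","W","P","J","U","V","R","T","M","D","F","C","A","N","K","G","E","B","O","H","S","L"]},"inquiries":{"sender":[1,1,1,1,1,1,2,2,2,2,3,3,3,4,4,4,5,5,5,5,6,6,7,7,7,7,7,8,8,8,9,10,10,10,11,11,11,11,12,12,12,13,13,14,14,14,14,15,17,17,17,18,18,19,19,19,19,19,19,20,20,20,20,21,21,21,21,21,21,21,22,22,23,24,24,24,24,25],"receiver":[7,2,20,23,5,14,12,17,1,21,15,4,8,13,3,16,25,18,1,4,25,7,14,12,6,1,22,24,17,7,10,15,9,23,12,5,17,15,13,6,22,9,4,13,7,18,15,10,7,11,18,17,19,20,18,23,6,3,12,19,16,8,25,25,22,9,18,2,15,16,21,23,14,23,25,8,11,6]},"replies":{"sender":[2,3,7,11,12,15,16,23],"receiver":[21,19,1,17,11,3,4,10],"kind":["referral","referral","referral","self_expert","referral","referral","referral","referral"],"named_player":[1,4,8,null,7,14,21,19]}},{"round":6,"assignment":{"player_order":[22,1,14,10,12,8,7,25,3,21,16,23,4,5,2,19,9,18,17,15,13,24,6,20,11],"letter_order":["P","U","H","N","B","D","S","V","G","F","X","T","J","A","Q","C","K","R","M","E","L","O","Y","W","I"],"question":["U","Q","G","J","A","Y","S","D","K","N","I","B","L","H","E","X","M","R","C","W","F","P","T","O","V"],"expertise":["H","C","F","A","Q","W","V","S","R","B","P","D","O","N","L","T","E","M","K","I","X","U","J","Y","G"]},"inquiries":{"sender":[1,1,1,1,1,2,2,2,2,2,3,3,4,4,5,6,6,6,6,6,6,7,7,8,8,8,8,9,9,9,9,10,10,10,10,11,12,12,12,12,12,12,13,13,14,14,15,15,15,15,16,16,16,16,17,17,17,17,18,18,18,19,19,20,20,20,20,21,21,21,21,21,21,21,21,22,23,23,23,23,24,24,25,25,25,25,25],"receiver":[9,4,7,2,22,21,10,6,1,12,4,15,16,25,25,7,25,3,19,12,23,18,12,24,20,9,7,23,13,7,12,15,21,1,23,17,13,4,2,7,3,22,19,3,21,13,11,3,1,21,25,20,12,13,8,19,15,25,12,1,22,18,20,11,16,25,15,5,9,14,2,22,24,10,25,4,20,19,2,1,8,23,1,13,7,14,18]},"replies":{"sender":[3,4,7,10,12,14,18,20,20,21,22,23,25,25],"receiver":[13,1,8,2,18,25,25,16,23,10,1,6,16,20],"kind":["referral","referral","referral","uninformed","referral","uninformed","referral","uninformed","referral","referral","self_expert","referral","referral","referral"],"named_player":[15,22,12,null,9,null,7,null,16,14,null,24,21,6]}}]}
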